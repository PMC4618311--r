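test_that("conditioning normalizes, averages and is near-idempotent", {
  s <- seq(-5, 5, length.out = 201)
  raw <- matrix(20 + 80 * exp(-s^2 / 2), 1, 201, byrow = TRUE)
  cp <- condition_profile(raw, s_um = s)
  expect_equal(min(cp$gamma), 0)
  expect_equal(max(cp$gamma), 1)
  expect_error(condition_profile(matrix(5, 3, 201), s_um = s), "flat")
  # averaging n frames shrinks the deviation like 1/sqrt(n)
  dev_n <- function(n, seed) {
    set.seed(seed)
    fr <- matrix(rep(100 * exp(-s^2 / 2), each = n), n, 201) +
      matrix(rnorm(n * 201, 0, 25), n, 201)
    cpn <- condition_profile(fr, s_um = s)
    sqrt(mean((cpn$gamma - exp(-s^2 / 2))^2))
  }
  d4 <- mean(sapply(1:5, dev_n, n = 4))
  d64 <- mean(sapply(1:5, dev_n, n = 64))
  # the noise part averages down; a small smoothing-bias floor remains
  expect_lt(d64, 0.65 * d4)
  expect_lt(d64, 0.05)
  # idempotence up to the (weak) smoothing
  cp2 <- condition_profile(matrix(cp$gamma, 1), s_um = s)
  expect_lt(max(abs(cp2$gamma - cp$gamma)), 0.05)
})

test_that("central width agrees with the exhaustive oracle on random profiles", {
  for (seed in 1:100) {
    pr <- random_profile(seed)
    cell <- diff(pr$s_um[1:2])
    for (f in c(0.5, 0.95)) {
      got <- central_width(pr, f)
      want <- central_width_oracle(pr$s_um, pr$gamma, f)
      expect_lt(abs(got - want), cell + 1e-9)
    }
    # monotone in the fraction
    expect_gte(central_width(pr, 0.95), central_width(pr, 0.5))
  }
})

test_that("central width is scale-equivariant and amplitude-invariant", {
  pr <- random_profile(7)
  w <- central_width(pr, 0.5)
  stretched <- data.frame(s_um = 3 * pr$s_um, gamma = pr$gamma)
  expect_equal(central_width(stretched, 0.5), 3 * w, tolerance = 1e-9)
  scaled <- data.frame(s_um = pr$s_um, gamma = 10 * pr$gamma)
  expect_equal(central_width(scaled, 0.5), w, tolerance = 1e-12)
  expect_error(central_width(data.frame(s_um = 1:5, gamma = rep(0, 5))),
               "zero")
})

test_that("area correction is constant on a cylinder and flattens a cap", {
  m <- cap_cylinder_meridian(2, flank = 6, n = 241)
  pr <- data.frame(s_um = seq(4, 8, length.out = 50),
                   intensity = exp(-(seq(4, 8, length.out = 50) - 6)^2))
  ac <- area_correct(pr, m, h = 0.3)
  expect_equal(ac$intensity / pr$intensity,
               rep(ac$intensity[1] / pr$intensity[1], 50), tolerance = 1e-9)
  # uniform surface density on the cap: recorded intensity prop to the
  # area element; correction recovers a flat profile
  prc <- data.frame(s_um = seq(0.2, 2.8, length.out = 60))
  kt <- approx(m$s, m$kappa_theta, xout = prc$s_um)$y
  prc$intensity <- sqrt(2 * 0.3 / kt) * median(diff(prc$s_um))
  acc <- area_correct(prc, m, h = 0.3)
  expect_lt(diff(range(acc$intensity)) / mean(acc$intensity), 0.02)
})

test_that("profile extraction sees a flat membrane marker and a cortical spot", {
  sc <- quiet_scenario(seed = 12, n_frames = 1)
  syn <- synth_cell_image_stack(sc)
  out <- syn$outlines[[1]]
  prof <- extract_profile(syn$stack[[1]], out, h = 0.3)
  # uniform band: flat profile away from resampling edges
  core <- prof$intensity[abs(prof$s_um) < 4]
  expect_lt(stats::sd(core) / mean(core), 0.05)
  # zero image gives a zero profile
  z <- extract_profile(matrix(0, nrow(syn$stack[[1]]), ncol(syn$stack[[1]])),
                       out, h = 0.3)
  expect_true(all(z$intensity == 0))
  # Gaussian cortical spot at the pole is recovered near s = 0
  px <- attr(out, "pixel_size")
  img <- syn$stack[[1]] * 0
  pole <- locate_pole(syn$outlines[[1]], syn$outlines[[1]] |>
                        (\(o) {o$x <- o$x + 0.5 / px; o})())
  res <- resample_outline(out, spacing = 1)
  i0 <- which.max(res$x)
  xs <- matrix(seq_len(ncol(img)) - 1, nrow(img), ncol(img), byrow = TRUE)
  ys <- matrix(seq_len(nrow(img)) - 1, nrow(img), ncol(img))
  img <- 100 * exp(-((xs - res$x[i0])^2 + (ys - res$y[i0])^2) / (2 * (0.5 / px)^2))
  sp <- extract_profile(img, out, h = 0.5)
  expect_lt(abs(sp$s_um[which.max(sp$intensity)]), 0.5)
})

test_that("advection: dual routes agree and chi -> gamma^alpha as k grows", {
  m <- cap_cylinder_meridian(2, flank = 6, n = 241)
  vp <- velocity_profile(0.05, -0.01)
  s <- seq(0, 9, length.out = 200)
  gp <- data.frame(s_um = s, gamma = exp(-s^2 / 2))
  sup_prev <- Inf
  for (k in c(0.5, 2, 10, 50, 250)) {
    ad <- advect_profile(gp, vp, m, k = k, deposition_exponent = 1.3)
    expect_lt(attr(ad, "max_rel_diff"), 1e-4)
    gam <- approx(s, gp$gamma^1.3, xout = ad$s_um, rule = 2)$y
    sup <- max(abs(ad$chi_ode / max(ad$chi_ode) - gam / max(gam)))
    expect_lt(sup, sup_prev + 1e-9)   # monotone convergence in k
    sup_prev <- sup
  }
  expect_lt(sup_prev, 0.02)
  # k = 0: on the flank (v = 1, r const) chi is proportional to the
  # cumulative integral of gamma * r; compare shapes anchored at the
  # start of the flank
  ad0 <- advect_profile(gp, velocity_profile(0, 0), m, k = 0)
  cum <- as.numeric(pracma::cumtrapz(s, gp$gamma *
                                       approx(m$s, m$r, xout = s, rule = 2)$y))
  ref <- approx(s, cum, xout = ad0$s_um)$y /
    (vp_eval(velocity_profile(0, 0), phi_of_s(m)(ad0$s_um)) *
       approx(m$s, m$r, xout = ad0$s_um, rule = 2)$y)
  on_flank <- which(ad0$s_um > 3.5 & ad0$s_um < 8.5)
  i0 <- on_flank[1]
  expect_equal(ad0$chi_ode[on_flank] / ad0$chi_ode[i0],
               ref[on_flank] / ref[i0], tolerance = 1e-3)
})

test_that("marker clustering separates two synthetic families", {
  sc <- synthetic_scenario(seed = 21, noise_sd = list(image = 0, track = 0,
                                                      profile = 3, contour = 0))
  profs <- list()
  for (i in 1:3) {
    raw <- synth_fluorescence_profiles("gaussian", list(sigma = 0.7 + 0.05 * i),
                                       1, 4, synthetic_scenario(seed = 21 + i,
                                                                noise_sd = sc$noise_sd))
    profs[[sprintf("narrow%d", i)]] <- condition_profile(raw[[1]])
    raw2 <- synth_fluorescence_profiles("cosine_power", list(W = 3.6 + 0.2 * i, p = 1),
                                        1, 4, synthetic_scenario(seed = 51 + i,
                                                                 noise_sd = sc$noise_sd))
    profs[[sprintf("broad%d", i)]] <- condition_profile(raw2[[1]])
  }
  dend <- compare_and_cluster_markers(profs, "width_features")
  cl <- stats::cutree(dend$hclust, k = 2)
  expect_equal(length(unique(cl[grep("narrow", names(cl))])), 1)
  expect_equal(length(unique(cl[grep("broad", names(cl))])), 1)
  expect_setequal(dend$labels, names(profs))
  # metric axioms on the distance matrix
  D <- dend$dist
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # identical profiles merge at zero height
  two <- list(a = profs[[1]], b = profs[[1]])
  d0 <- compare_and_cluster_markers(two, "width_features")
  expect_equal(max(d0$dist), 0)
  expect_equal(d0$hclust$height, 0)
})

test_that("ergodicity check flags mixtures but not same-generator samples", {
  set.seed(31)
  flags <- sapply(1:8, function(i) {
    a <- rnorm(25, 2.5, 0.2)
    b <- rnorm(25, 2.5, 0.2)
    ergodicity_check(a, b)$flagged
  })
  expect_lt(mean(flags), 0.3)
  mixed <- ergodicity_check(rnorm(40, 1.8, 0.1),
                            c(rnorm(20, 1.8, 0.1), rnorm(20, 3.2, 0.1)))
  expect_true(mixed$flagged)
  same <- ergodicity_check(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
})

test_that("fwha-width trends are recovered per genotype", {
  set.seed(41)
  widths <- rep(c(3, 4, 5), each = 30)
  # proportional marker
  d1 <- data.frame(genotype = rep(c("narrow", "wt", "wide"), each = 30),
                   width = widths,
                   fwha = 0.6 * widths + rnorm(90, 0, 0.1))
  r1 <- fwha_vs_width(d1)
  expect_gt(r1$slope_ci[1], 0.5)
  expect_lt(r1$slope_ci[2], 0.7)
  # width-independent marker
  d2 <- d1; d2$fwha <- 2 + rnorm(90, 0, 0.1)
  r2 <- fwha_vs_width(d2)
  expect_lt(abs(r2$slope), 0.05)
  expect_equal(sort(r2$groups$fwha_mean),
               sort(unname(sapply(split(d2$fwha, d2$genotype), mean))),
               tolerance = 1e-12)
  single <- fwha_vs_width(d1[d1$genotype == "wt", ])
  expect_true(is.na(single$slope))
})
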