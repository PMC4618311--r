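test_that("thin-cylinder estimator reproduces the printed worked example", {
  est <- cylinder_estimator(0.13, 0.24)
  expect_equal(est$nu, -0.0571, tolerance = 1e-3)
  expect_equal(round(est$nu, 2), -0.06)
  expect_equal(est$E_over_P, 44, tolerance = 0.01)
  # rho = 2 gives nu = 0
  expect_equal(cylinder_estimator(0.1, 0.2)$nu, 0)
  # boundaries
  expect_error(cylinder_estimator(0.2, 0.09), "thin-cylinder")
  expect_error(cylinder_estimator(0.1, 0.1), "-1")
})

test_that("shell energy gradient matches finite differences", {
  set.seed(3)
  m <- cap_cylinder_meridian(2, flank = 3, n = 31)
  params <- elastic_params(58, 0.07)
  for (model in c("membrane", "bending_shear")) {
    sp <- wallmorph:::.shell_spec(m$r, m$z, params, 1, model, "symmetry")
    r <- m$r + c(0, rnorm(30, 0, 0.02))
    z <- m$z + rnorm(31, 0, 0.02)
    g <- wallmorph:::.shell_energy(r, z, sp, grad = TRUE)
    h <- 1e-6
    for (i in c(1, 7, 18, 31)) {
      rp <- r; rp[i] <- r[i] + h; rm <- r; rm[i] <- r[i] - h
      num <- (wallmorph:::.shell_energy(rp, z, sp) -
                wallmorph:::.shell_energy(rm, z, sp)) / (2 * h)
      expect_equal(g$g_r[i], num, tolerance = 1e-5)
      zp <- z; zp[i] <- z[i] + h; zm <- z; zm[i] <- z[i] - h
      num <- (wallmorph:::.shell_energy(r, zp, sp) -
                wallmorph:::.shell_energy(r, zm, sp)) / (2 * h)
      expect_equal(g$g_z[i], num, tolerance = 1e-5)
    }
  }
})

test_that("inflation matches pressure-vessel closed forms at small strain", {
  params <- elastic_params(58, 0.1)
  R <- 2; P <- 0.02
  C <- params$E_over_P * params$thickness_to_radius * R
  m <- cap_cylinder_meridian(R, flank = 10, n = 121)
  sol <- inflate_shell(m, params, pressure = P)
  s_mid <- cumsum(sqrt(diff(m$r)^2 + diff(m$z)^2))
  idx <- which(s_mid > 8 & s_mid < 11)
  et <- mean(sol$lambda_theta[idx] - 1)
  es <- mean(sol$lambda_s[idx] - 1)
  expect_equal(et, P * R / C * (1 - params$nu / 2), tolerance = 0.02)
  expect_equal(es, P * R / C * (0.5 - params$nu), tolerance = 0.02)
  # sphere: uniform isotropic strain
  ms <- cap_cylinder_meridian(R, flank = 0, n = 81)
  ss <- inflate_shell(ms, params, pressure = P)
  eps <- ss$lambda_s[20:60] - 1
  expect_equal(mean(eps), P * R / (2 * C) * (1 - params$nu),
               tolerance = 0.02)
  # zero pressure is the identity
  id <- inflate_shell(m, params, pressure = 0)
  expect_equal(id$r, m$r)
  expect_equal(id$z, m$z)
})

test_that("membrane solution is insensitive to re-discretization", {
  params <- elastic_params(58, 0.1)
  P <- 0.02
  ets <- sapply(c(121, 241), function(n) {
    m <- cap_cylinder_meridian(2, flank = 10, n = n)
    sol <- inflate_shell(m, params, pressure = P)
    s_mid <- cumsum(sqrt(diff(m$r)^2 + diff(m$z)^2))
    mean(sol$lambda_theta[s_mid > 8 & s_mid < 11] - 1)
  })
  expect_lt(abs(ets[2] / ets[1] - 1), 0.005)
})

test_that("response is linear at very small pressure", {
  params <- elastic_params(58, 0.03)
  m <- cap_cylinder_meridian(2, flank = 4, n = 61)
  d_at <- function(P) {
    sol <- inflate_shell(m, params, pressure = P)
    mean(sol$lambda_theta - 1)
  }
  P0 <- 0.01   # P/E ~ 2e-4: well inside the linear regime
  expect_equal(d_at(2 * P0) / d_at(P0), 2, tolerance = 0.01)
})

test_that("elastic parameters are recovered from noisy contour pairs", {
  truth <- elastic_params(58, 0.03)
  res <- sapply(1:6, function(sd) {
    pair <- synth_plasmolysis_pair(truth, noise_sd = 0.02, seed = sd)
    est <- suppressWarnings(
      fit_elastic_params(pair$plasmolysed, pair$turgid, grid_n = 4))
    c(est$E_over_P, est$nu)
  })
  expect_lt(abs(mean(res[1, ]) / 58 - 1), 0.1)
  expect_lt(abs(mean(res[2, ]) - 0.03), 0.05)
})

test_that("a mismatched contour pair is flagged", {
  truth <- elastic_params(58, 0.03)
  a <- synth_plasmolysis_pair(truth, resting = cap_cylinder_meridian(2, flank = 4, n = 61))
  b <- synth_plasmolysis_pair(truth, resting = cap_cylinder_meridian(1.4, flank = 5, n = 61))
  w <- capture_warnings(
    fit_elastic_params(a$plasmolysed_meridian, b$turgid_meridian,
                       grid_n = 3))
  expect_true(any(grepl("mismatch|bounds", w)))
})

test_that("septum inflation is monotone in resting length and shows the scar", {
  p <- elastic_params(58, 0.03)
  defl <- sapply(c(1, 1.15, 1.3, 1.45), function(f)
    inflate_septum(2, f, p)$pole_deflection)
  expect_true(all(diff(defl) > 0))
  s13 <- inflate_septum(2, 1.3, p)
  expect_gt(s13$pole_curvature, 0)
  # near-hemispherical cap: deflection comparable to the radius
  expect_gt(s13$pole_deflection, 1.2)
  expect_lt(s13$pole_deflection, 2.2)
  # curvature ridge (division scar) near the junction: an interior local
  # maximum in the outer third of the meridian
  kp <- s13$kappa_profile
  outer <- kp[kp$s_um > 0.6 * max(kp$s_um), ]
  i_max <- which.max(outer$kappa_s)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(outer))
  expect_gt(max(outer$kappa_s), 1.2 * s13$pole_curvature)
  # stiff flat septum stays nearly flat
  flat <- inflate_septum(2, 1, elastic_params(5000, 0.03))
  expect_lt(flat$pole_deflection, 0.25)
  expect_error(inflate_septum(2, 0.9, p), ">= 1")
})
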