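test_that("turning-angle curvature recovers circle and line values", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  oc <- planar_outline(40 + 20 * cos(th), 40 + 20 * sin(th),
                       pixel_size = 0.1)   # radius 2 um
  k <- meridional_curvature(oc)
  expect_true(all(abs(k$kappa_s - 0.5) < 0.005))
  # straight segments of a long thin rectangle have ~zero curvature
  ox <- c(seq(5, 55, by = 1), rep(55, 11), seq(55, 5, by = -1), rep(5, 11))
  oy <- c(rep(5, 51), seq(5, 15, by = 1), rep(15, 51), seq(15, 5, by = -1))
  keep <- !duplicated(cbind(ox, oy))
  rect <- planar_outline(ox[keep], oy[keep], pixel_size = 0.1)
  kr <- meridional_curvature(rect)
  # most of the perimeter is straight (spline ringing near the corners
  # leaves tiny residual curvature elsewhere)
  expect_lt(stats::median(abs(kr$kappa_s)), 0.02)
  # the printed-arithmetic identity kappa = alpha / l
  expect_equal(0.00335 / 0.0067, 0.5)
})

test_that("pole sits on the symmetry axis for axial growth", {
  sc <- quiet_scenario(seed = 2, n_frames = 6, dh_mean = 0.5)
  syn <- synth_cell_image_stack(sc)
  first <- syn$outlines[[1]]; last <- syn$outlines[[6]]
  pole <- locate_pole(first, last)
  px <- attr(first, "pixel_size")
  # axis is horizontal at the vertical image centre; growing end = right
  y_axis <- mean(first$y)
  expect_lt(abs(pole$point["y"] - y_axis) * px, 0.15)
  expect_gt(pole$point["x"], max(first$x) - 2)
  expect_equal(pole$path_length * px, sum(syn$growth), tolerance = 0.1)
})

test_that("identical outlines leave the pole undefined", {
  sc <- quiet_scenario(seed = 3, n_frames = 4, dh_mean = 0)
  syn <- synth_cell_image_stack(sc)
  expect_error(locate_pole(syn$outlines[[1]], syn$outlines[[4]]),
               "no growth")
})

test_that("orthogonal-path search agrees with a brute-force oracle", {
  sc <- quiet_scenario(seed = 4, n_frames = 5, dh_mean = 0.45)
  syn <- synth_cell_image_stack(sc)
  a <- resample_outline(syn$outlines[[1]], spacing = 0.5)
  b <- resample_outline(syn$outlines[[5]], spacing = 0.5)
  pole <- locate_pole(syn$outlines[[1]], syn$outlines[[5]], spacing = 0.5)
  # oracle: march along each outward normal in small steps until crossing
  # the other polygon (point-in-polygon flip)
  inside <- function(px, py, qx, qy) {
    n <- length(qx); j <- n; ins <- FALSE
    for (i in seq_len(n)) {
      if ((qy[i] > py) != (qy[j] > py) &&
          px < (qx[j] - qx[i]) * (py - qy[i]) / (qy[j] - qy[i]) + qx[i])
        ins <- !ins
      j <- i
    }
    ins
  }
  n <- nrow(a)
  tx <- (a$x[c(2:n, 1)] - a$x[c(n, 1:(n - 1))])
  ty <- (a$y[c(2:n, 1)] - a$y[c(n, 1:(n - 1))])
  tl <- sqrt(tx^2 + ty^2)
  nx <- ty / tl; ny <- -tx / tl   # one normal orientation
  best <- 0
  for (i in seq(1, n, by = 4)) {
    # outward direction: a small step along it leaves polygon A
    sgn <- if (inside(a$x[i] + 0.3 * nx[i], a$y[i] + 0.3 * ny[i],
                      a$x, a$y)) -1 else 1
    t <- 0
    repeat {
      t <- t + 0.05
      if (t > 60) { t <- NA; break }
      if (!inside(a$x[i] + sgn * t * nx[i], a$y[i] + sgn * t * ny[i],
                  b$x, b$y)) break
    }
    if (!is.na(t) && t > best) best <- t
  }
  expect_equal(pole$path_length, best, tolerance = 0.15)
})

test_that("canonical end shape symmetrizes and tightens as 1/sqrt(N)", {
  set.seed(11)
  R <- 2
  s <- seq(-pi, pi, length.out = 201)
  make_prof <- function() data.frame(s_um = s,
                                     kappa_s = 1 / R + rnorm(201, 0, 0.05))
  for (N in c(8, 32)) {
    profs <- replicate(N, make_prof(), simplify = FALSE)
    cs <- canonical_end_shape(profs)
    expect_equal(mean(cs$kappa_mean), 0.5, tolerance = 0.02)
    if (N == 8) sd8 <- mean(cs$kappa_sd / sqrt(cs$n))
    if (N == 32) sd32 <- mean(cs$kappa_sd / sqrt(cs$n))
  }
  expect_lt(sd32, sd8)
  # asymmetric input: output equals the mean of mirrored halves
  p <- data.frame(s_um = seq(-1, 1, length.out = 101),
                  kappa_s = seq(0, 2, length.out = 101))
  cs <- canonical_end_shape(list(p), s_grid = seq(0, 1, length.out = 21))
  expect_equal(cs$kappa_mean, rep(1, 21), tolerance = 1e-6)
})

test_that("kymograph of a static shape has identical columns", {
  p <- data.frame(s_um = seq(-3, 3, length.out = 101),
                  kappa_s = exp(-seq(-3, 3, length.out = 101)^2))
  kym <- curvature_kymograph(list(p, p, p, p), times = 1:4)
  expect_equal(kym$kappa[, 1], kym$kappa[, 4])
  expect_false(any(kym$missing))
  # a frame without pole is flagged
  kym2 <- curvature_kymograph(list(p, NULL, p), times = 1:3)
  expect_true(kym2$missing[2])
  expect_true(all(is.na(kym2$kappa[, 2])))
})

test_that("outline tracking recovers synthetic outlines within a pixel", {
  sc <- quiet_scenario(seed = 5, n_frames = 3, dh_mean = 0.3)
  syn <- synth_cell_image_stack(sc)
  init <- resample_outline(syn$outlines[[1]], n = 50)
  tracked <- track_outlines(syn$stack, init)
  for (f in 1:3) {
    truth <- resample_outline(syn$outlines[[f]], n = 200)
    got <- resample_outline(tracked[[f]], n = 200)
    d <- sapply(seq_len(200), function(i)
      min(sqrt((truth$x - got$x[i])^2 + (truth$y - got$y[i])^2)))
    expect_lt(sqrt(mean(d^2)), 1)
  }
})

test_that("tracking is inert on a featureless image and recovers a 3 px offset", {
  sc <- quiet_scenario(seed = 6, n_frames = 1)
  syn <- synth_cell_image_stack(sc)
  init <- resample_outline(syn$outlines[[1]], n = 40)
  flat <- matrix(7, nrow(syn$stack[[1]]), ncol(syn$stack[[1]]))
  same <- track_outlines(list(flat), init)
  expect_equal(same[[1]]$x, init$x)
  expect_equal(same[[1]]$y, init$y)
  # displaced start converges back onto the band
  off <- planar_outline(init$x + 3, init$y,
                        pixel_size = attr(init, "pixel_size"))
  back <- track_outlines(syn$stack[1], off, max_sweeps = 120)
  truth <- resample_outline(syn$outlines[[1]], n = 200)
  got <- resample_outline(back[[1]], n = 200)
  d <- sapply(seq_len(200), function(i)
    min(sqrt((truth$x - got$x[i])^2 + (truth$y - got$y[i])^2)))
  expect_lt(stats::median(d), 1)
})
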