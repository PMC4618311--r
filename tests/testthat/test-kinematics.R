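test_that("relative displacement is ds/dh with zero-growth intervals excluded", {
  m <- hemi_meridian()
  tr <- qdot_track(s_um = c(1, 1.5, 1.5, 2.5), dh_um = c(0.5, 0, 1))
  expect_warning(rd <- relative_displacement(tr, m), "excluded")
  expect_equal(rd$v, c(1, 1))
  # pole-resident track
  trp <- qdot_track(s_um = c(0, 0, 0), dh_um = c(0.4, 0.4))
  rdp <- relative_displacement(trp, m)
  expect_equal(rdp$v, c(0, 0))
  # flank: ds = dh -> v = 1 (equator normalization)
  trf <- qdot_track(s_um = c(5, 5.5), dh_um = 0.5)
  expect_equal(relative_displacement(trf, m)$v, 1)
})

test_that("constrained velocity fit recovers coefficients exactly", {
  phi <- seq(0.1, pi / 2, length.out = 40)
  for (bc in list(c(0, 0), c(0.15, -0.03), c(-0.2, 0.05))) {
    vp <- velocity_profile(b = bc[1], c = bc[2])
    fit <- fit_velocity_profile(data.frame(phi = phi, v = vp_eval(vp, phi)))
    expect_equal(fit$b, bc[1], tolerance = 1e-10)
    expect_equal(fit$c, bc[2], tolerance = 1e-10)
    # the equator constraint holds to machine precision
    expect_equal(fit$a + fit$b * (pi / 2)^2 + fit$c * (pi / 2)^4, 1,
                 tolerance = 1e-14)
  }
  expect_error(fit_velocity_profile(
    data.frame(phi = rep(1, 5), v = rep(0.8, 5))), "degenerate")
})

test_that("strain rates on the unit hemisphere are isotropic cos(phi)", {
  m <- cap_cylinder_meridian(1, flank = 2, n = 401)
  vp <- velocity_profile(0, 0)          # v = sin(phi)
  pr <- strain_rates(vp, m)
  cap <- which(m$s < pi / 2 - 0.1 & m$s > 0.05)
  expect_equal(pr$eps_s[cap], cos(m$phi[cap]), tolerance = 0.01)
  expect_equal(pr$eps_theta[cap], cos(m$phi[cap]), tolerance = 0.01)
  expect_true(all(abs(pr$alpha_aniso[cap]) < 0.02))
  # cylinder flank, v = 1: no expansion below the growth zone
  flank <- which(m$s > pi / 2 + 0.3)
  expect_true(all(abs(pr$eps_s[flank]) < 1e-6))
  expect_true(all(abs(pr$eps_theta[flank]) < 1e-6))
  # areal expansion is the sum by definition, pointwise
  pr2 <- strain_rates(velocity_profile(0.2, -0.04), hemi_meridian())
  expect_equal(pr2$areal, pr2$eps_s + pr2$eps_theta)
})

test_that("expansion fraction matches a quadrature oracle on uniform A", {
  R <- 2
  m <- cap_cylinder_meridian(R, flank = 0, n = 801)
  vp <- velocity_profile(0, 0)
  pr <- strain_rates(vp, m)
  d <- max(m$s) / 2
  es <- expansion_summary(pr, m, d = d)
  # oracle: A = (2/R) cos(s/R), weight 2 pi R sin(s/R)
  num <- integrate(function(s) (2 / R) * cos(s / R) * 2 * pi * R * sin(s / R),
                   0, d)$value
  den <- integrate(function(s) (2 / R) * cos(s / R) * 2 * pi * R * sin(s / R),
                   0, max(m$s))$value
  expect_equal(es$fraction$fraction, num / den, tolerance = 0.01)
  # delta-like concentration near the pole -> fraction 1
  prd <- pr
  prd$areal <- exp(-(m$s / 0.05)^2)
  esd <- expansion_summary(prd, m, d = 1)
  expect_gt(esd$fraction$fraction, 0.999)
})

test_that("normalizing by growth increments collapses fluctuating tracks", {
  m <- hemi_meridian(n = 481)
  vp <- velocity_profile(b = 0.1, c = -0.02)
  pooled <- function(fluct, seed) {
    sc <- synthetic_scenario(seed = seed, n_frames = 14, dh_mean = 0.35,
                             fluctuation = fluct,
                             noise_sd = list(image = 0, track = 0.03,
                                             profile = 0, contour = 0))
    tracks <- synth_qdot_tracks(vp, m, 10, sc)
    do.call(rbind, lapply(tracks, relative_displacement, meridian = m))
  }
  resid_var <- function(samples) {
    fit <- fit_velocity_profile(samples)
    mean((samples$v - vp_eval(fit, samples$phi))^2)
  }
  v0 <- mean(sapply(1:4, function(s) resid_var(pooled(0, s))))
  v5 <- mean(sapply(1:4, function(s) resid_var(pooled(0.5, s))))
  # residual variance is set by the track noise, not by the growth
  # fluctuations (master-curve collapse)
  expect_gt(v5 / v0, 0.4)
  expect_lt(v5 / v0, 2.5)
  # noiseless fluctuating tracks collapse exactly
  sc0 <- quiet_scenario(seed = 9, n_frames = 10, dh_mean = 0.4,
                        fluctuation = 0.5)
  tr <- synth_qdot_tracks(vp, m, 8, sc0)
  sm <- do.call(rbind, lapply(tr, relative_displacement, meridian = m))
  expect_lt(max(abs(sm$v - vp_eval(vp, sm$phi))), 1e-12)
})

test_that("coefficient recovery from noisy tracks is consistent", {
  m <- hemi_meridian(n = 481)
  vp <- velocity_profile(b = 0.12, c = -0.025)
  est <- function(n_tracks, seed, noise) {
    sc <- synthetic_scenario(seed = seed, n_frames = 12, dh_mean = 0.4,
                             fluctuation = 0.3,
                             noise_sd = list(image = 0, track = noise,
                                             profile = 0, contour = 0))
    tracks <- synth_qdot_tracks(vp, m, n_tracks, sc)
    s <- do.call(rbind, lapply(tracks, relative_displacement, meridian = m))
    fit <- fit_velocity_profile(s)
    c(fit$b, fit$c)
  }
  # dispersion across seeds shrinks with the number of tracks
  small <- sapply(1:6, function(s) est(4, s, 0.02))
  large <- sapply(1:6, function(s) est(40, s + 100, 0.02))
  expect_lt(stats::sd(large[1, ]), stats::sd(small[1, ]))
  # position noise enters the regressors, so a small bias remains; it
  # shrinks with the noise level
  b_lo <- abs(mean(large[1, ]) - 0.12)
  big_noise <- sapply(1:6, function(s) est(40, s + 200, 0.08))
  expect_lt(b_lo, abs(mean(big_noise[1, ]) - 0.12))
  expect_lt(b_lo, 0.03)
  expect_lt(abs(mean(large[2, ]) + 0.025), 0.02)
})
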