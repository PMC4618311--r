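# shared fixtures, built in code at test time

hemi_meridian <- function(R = 2, flank = 6, n = 241)
  cap_cylinder_meridian(R, flank = flank, n = n)

quiet_scenario <- function(seed = 1, ...) {
  synthetic_scenario(seed = seed,
                     noise_sd = list(image = 0, track = 0, profile = 0,
                                     contour = 0), ...)
}

# independent oracle for the central-area width: scan candidate left
# boundaries, place the right boundary so lateral areas are equal, and
# keep the candidate whose central area is closest to the target fraction
central_width_oracle <- function(s, y, fraction) {
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(s)))
  tot <- cum[length(cum)]
  qL <- (1 - fraction) / 2
  grid <- seq(0, qL * 1.9999, length.out = 4000)
  best <- Inf; width <- NA
  inv <- function(f) {
    target <- f * tot
    i <- findInterval(target, cum, all.inside = TRUE)
    s[i] + (target - cum[i]) / max(cum[i + 1] - cum[i], 1e-300) *
      (s[i + 1] - s[i])
  }
  for (a in grid) {
    sl <- inv(a); sr <- inv(1 - a)
    cen <- (1 - 2 * a)
    err <- abs(cen - fraction)
    if (err < best) { best <- err; width <- sr - sl }
  }
  width
}

# random smooth non-negative profile on a symmetric grid
random_profile <- function(seed, n = 301, smax = 6) {
  set.seed(seed)
  s <- seq(-smax, smax, length.out = n)
  y <- rep(0, n)
  for (k in 1:4) {
    y <- y + runif(1, 0.2, 1) * exp(-(s - runif(1, -2, 2))^2 /
                                      (2 * runif(1, 0.3, 2)^2))
  }
  data.frame(s_um = s, gamma = y)
}
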