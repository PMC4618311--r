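#' Meridional velocity profile of wall elements
#'
#' The relative meridional displacement of wall elements at a growing end
#' is described by `v(phi) = sin(phi) * (a + b*phi^2 + c*phi^4)`, where
#' `phi` is the angle of the normal to the cell contour. The normalization
#' constraint `v(pi/2) = a + b*(pi/2)^2 + c*(pi/2)^4 = 1` (relative
#' displacement 1 at the equator) is enforced exactly: `a` is always
#' computed from `b` and `c`.
#'
#' @param b,c polynomial coefficients (dimensionless).
#' @return An object of class `velocity_profile` with fields `a`, `b`, `c`.
#' @export
velocity_profile <- function(b = 0, c = 0) {
  a <- 1 - b * (pi / 2)^2 - c * (pi / 2)^4
  structure(list(a = a, b = b, c = c), class = "velocity_profile")
}

#' Evaluate a velocity profile
#' @param vp a [velocity_profile()].
#' @param phi normal angle(s), rad.
#' @return `v(phi)`.
#' @export
vp_eval <- function(vp, phi) {
  sin(phi) * (vp$a + vp$b * phi^2 + vp$c * phi^4)
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("velocity_profile: v(phi) = sin(phi)(%.6g + %.6g phi^2 + %.6g phi^4)\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Fiducial (Qdot) track
#'
#' Per-frame meridional position of a wall-bound fiducial, together with
#' the per-interval tip growth increment.
#'
#' @param s_um meridional positions (um) per frame.
#' @param dh_um tip growth increments (um) per interval
#'   (`length(s_um) - 1` values, all >= 0).
#' @param id optional track identifier.
#' @return An object of class `qdot_track`.
#' @export
qdot_track <- function(s_um, dh_um, id = NA_character_) {
  stopifnot(length(dh_um) == length(s_um) - 1, all(dh_um >= 0))
  structure(list(s_um = s_um, dh_um = dh_um, id = id), class = "qdot_track")
}

#' Relative displacement samples from a fiducial track
#'
#' For a fiducial moving from `s` to `s + ds` while the tip advances by
#' `dh`, the relative displacement is `v = ds / dh`. Each interval yields
#' one sample attached to the interval's starting position, mapped to the
#' normal angle via the meridian. Intervals with `dh = 0` are excluded
#' (with a warning) since the ratio is undefined.
#'
#' @param track a [qdot_track()].
#' @param meridian a [meridian_contour()] used to map `s` to `phi`.
#' @return data frame with columns `s_um`, `phi`, `v`.
#' @export
relative_displacement <- function(track, meridian) {
  ds <- diff(track$s_um)
  dh <- track$dh_um
  keep <- dh > 0
  if (any(!keep)) warning(sprintf("%d zero-growth interval(s) excluded",
                                  sum(!keep)))
  s0 <- track$s_um[-length(track$s_um)][keep]
  f <- phi_of_s(meridian)
  data.frame(s_um = s0, phi = f(s0), v = ds[keep] / dh[keep])
}

#' Fit the constrained velocity profile to displacement samples
#'
#' Least squares for `v(phi) = sin(phi)(a + b phi^2 + c phi^4)` subject to
#' the equality constraint `v(pi/2) = 1`. The constraint is eliminated
#' exactly (`a = 1 - b (pi/2)^2 - c (pi/2)^4`), so it holds to machine
#' precision in the result.
#'
#' @param samples data frame with columns `phi` and `v` (e.g. from
#'   [relative_displacement()], possibly pooled over tracks).
#' @return A [velocity_profile()] with attributes `rss` (residual sum of
#'   squares) and `n` (number of samples).
#' @export
fit_velocity_profile <- function(samples) {
  stopifnot(nrow(samples) >= 3)
  phi <- samples$phi; v <- samples$v
  if (diff(range(phi)) < 1e-3) stop("degenerate sample spread in phi")
  h <- pi / 2
  y <- v - sin(phi)
  x1 <- sin(phi) * (phi^2 - h^2)
  x2 <- sin(phi) * (phi^4 - h^4)
  fit <- stats::lm.fit(cbind(x1, x2), y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  vp <- velocity_profile(b = unname(co[1]), c = unname(co[2]))
  attr(vp, "rss") <- sum(fit$residuals^2)
  attr(vp, "n") <- length(v)
  vp
}

#' Wall expansion (strain-rate) profile
#'
#' Converts a fitted velocity profile on a given meridian into the local
#' wall expansion rates, per unit tip advance: the meridional strain rate
#' `eps_s = dv/ds`, the circumferential strain rate
#' `eps_theta = v cos(phi) / r` (pole limit `dv/ds(0)` by l'Hopital), the
#' areal expansion `A = eps_s + eps_theta`, and the deformation anisotropy
#' `alpha_aniso = (w - l)/w` of a wall element that starts circular near
#' the pole (`w`, `l` are its evolving circumferential width and
#' meridional length; in closed form `w(s) = w0 r(s)/r(s0)` and
#' `l(s) = l0 v(s)/v(s0)`). The transit coordinate
#' `t(s) = int_{s0}^{s} dxi / v(xi)` is included (the pole is a
#' logarithmic singularity of the transit time, hence the offset `s0`).
#'
#' @param velocity a [velocity_profile()].
#' @param meridian a [meridian_contour()].
#' @param s0 starting offset for element trajectories and transit time
#'   (um; default: one grid cell from the pole).
#' @return An object of class `expansion_profile`: data frame with columns
#'   `s_um`, `v`, `eps_s`, `eps_theta`, `areal`, `alpha_aniso`, `w`, `l`,
#'   `transit`.
#' @export
strain_rates <- function(velocity, meridian, s0 = NULL) {
  s <- meridian$s
  if (any(meridian$r[-1] <= 0)) stop("meridian radius vanishes off-pole")
  v <- vp_eval(velocity, meridian$phi)
  eps_s <- as.numeric(pracma::gradient(v, s))
  eps_t <- c(eps_s[1], v[-1] * cos(meridian$phi[-1]) / meridian$r[-1])
  vprime0 <- eps_s[1]
  if (is.null(s0)) s0 <- s[2]
  alpha <- c(0, 1 - (v[-1] / meridian$r[-1]) / vprime0)
  i0 <- max(2L, findInterval(s0, s))
  w <- ifelse(s >= s[i0], meridian$r / meridian$r[i0], NA_real_)
  l <- ifelse(s >= s[i0], v / v[i0], NA_real_)
  tr <- rep(NA_real_, length(s))
  idx <- which(s >= s[i0])
  if (length(idx) >= 2)
    tr[idx] <- as.numeric(pracma::cumtrapz(s[idx], 1 / pmax(v[idx], 1e-12)))
  out <- data.frame(s_um = s, v = v, eps_s = eps_s, eps_theta = eps_t,
                    areal = eps_s + eps_t, alpha_aniso = alpha,
                    w = w, l = l, transit = tr)
  class(out) <- c("expansion_profile", "data.frame")
  out
}

#' Localization and anisotropy summary of an expansion profile
#'
#' Integrates the areal expansion with the surface weight `2 pi r ds` and
#' reports the fraction of total expansion within a distance `d` of the
#' pole, alongside the peak anisotropy and the wall-element dimension
#' trajectories.
#'
#' @param profile an [strain_rates()] expansion profile.
#' @param meridian the matching [meridian_contour()].
#' @param d distances from the pole (um) at which to evaluate the
#'   localization fraction.
#' @return A list with `fraction` (data frame d, fraction), `peak_aniso`,
#'   and `elements` (s, w, l).
#' @export
expansion_summary <- function(profile, meridian, d = 3) {
  s <- profile$s_um
  # areal expansion is a non-negative density; clip the small negative
  # excursions a fitted velocity can produce on the flank
  wgt <- pmax(profile$areal, 0) * 2 * pi * meridian$r
  cum <- as.numeric(pracma::cumtrapz(s, wgt))
  tot <- cum[length(cum)]
  if (abs(tot) < 1e-12) stop("total areal expansion is zero")
  frac <- stats::approx(s, cum / tot, xout = pmin(d, max(s)), rule = 2)$y
  list(fraction = data.frame(d_um = d, fraction = frac),
       peak_aniso = max(profile$alpha_aniso, na.rm = TRUE),
       elements = data.frame(s_um = s, w = profile$w, l = profile$l))
}
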