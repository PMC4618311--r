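#' Axisymmetric meridian contour
#'
#' A `meridian_contour` describes the profile curve of an axisymmetric
#' surface (a cell end, or a whole half-cell) in the meridional frame:
#' arclength `s` (um, 0 at the pole), normal angle `phi` (rad, angle of the
#' outward normal to the symmetry axis, 0 at the pole), radius `r` (um,
#' distance to the axis), axial coordinate `z` (um, decreasing away from the
#' pole), meridional curvature `kappa_s` (1/um) and circumferential
#' curvature `kappa_theta = sin(phi)/r` (1/um, with the pole limit
#' `kappa_theta(0) = kappa_s(0)`).
#'
#' @param s numeric vector of arclength positions, starting at 0,
#'   strictly increasing.
#' @param phi,r,z,kappa_s,kappa_theta numeric vectors of the same length.
#' @return An object of class `meridian_contour` (a data frame with the six
#'   columns above).
#' @seealso [reconstruct_meridian()], [cap_cylinder_meridian()]
#' @export
meridian_contour <- function(s, phi, r, z, kappa_s, kappa_theta) {
  n <- length(s)
  stopifnot(n >= 3, length(phi) == n, length(r) == n, length(z) == n,
            length(kappa_s) == n, length(kappa_theta) == n)
  if (abs(s[1]) > 1e-12 || abs(r[1]) > 1e-9 || abs(phi[1]) > 1e-6)
    stop("meridian must start at the pole: s(0)=0, r(0)=0, phi(0)=0")
  if (any(diff(s) <= 0)) stop("arclength grid must be strictly increasing")
  out <- data.frame(s = s, phi = phi, r = r, z = z,
                    kappa_s = kappa_s, kappa_theta = kappa_theta)
  class(out) <- c("meridian_contour", "data.frame")
  out
}

#' Reconstruct a meridian from its meridional curvature
#'
#' Integrates the standard axisymmetric relations
#' `phi(s) = int_0^s kappa_s dxi`, `r(s) = int_0^s cos(phi) dxi`,
#' `z(s) = -int_0^s sin(phi) dxi` and `kappa_theta = sin(phi)/r`
#' (pole limit `kappa_s(0)`), so that a measured (or designed) curvature
#' profile becomes a full surface-of-revolution profile curve.
#'
#' @param kappa_s numeric vector of meridional curvature samples, or a
#'   function of `s`.
#' @param s arclength grid on which `kappa_s` is defined (required if
#'   `kappa_s` is a function; must start at 0).
#' @return A [meridian_contour()].
#' @examples
#' # constant curvature 1/R over a quarter arc gives a hemisphere
#' R <- 2
#' s <- seq(0, pi * R / 2, length.out = 200)
#' m <- reconstruct_meridian(rep(1 / R, length(s)), s)
#' abs(m$r[nrow(m)] - R) < 1e-3
#' @export
reconstruct_meridian <- function(kappa_s, s) {
  if (is.function(kappa_s)) kappa_s <- kappa_s(s)
  stopifnot(length(kappa_s) == length(s), s[1] == 0)
  phi <- as.numeric(pracma::cumtrapz(s, kappa_s))
  if (any(phi > pi + 1e-9))
    stop("normal angle exceeds pi: meridian folds onto itself")
  r <- as.numeric(pracma::cumtrapz(s, cos(phi)))
  z <- -as.numeric(pracma::cumtrapz(s, sin(phi)))
  kt <- ifelse(r > 1e-9, sin(phi) / pmax(r, 1e-300), NA_real_)
  kt[1] <- kappa_s[1]
  # fill any remaining near-pole values by the pole limit
  kt[is.na(kt)] <- kappa_s[is.na(kt)]
  meridian_contour(s, phi, r, z, kappa_s, kt)
}

#' Hemispherical cap plus cylindrical flank
#'
#' Convenience constructor for the classic rod-end geometry: constant
#' meridional curvature `1/radius` over a quarter circle, then a straight
#' flank of length `flank` (curvature 0).
#'
#' @param radius cap/cylinder radius (um).
#' @param flank length of the cylindrical flank (um). May be 0.
#' @param n number of grid points.
#' @return A [meridian_contour()].
#' @export
cap_cylinder_meridian <- function(radius, flank = 2 * radius, n = 241) {
  stopifnot(radius > 0, flank >= 0)
  s_cap <- pi * radius / 2
  s <- seq(0, s_cap + flank, length.out = n)
  cap <- s <= s_cap
  phi <- ifelse(cap, s / radius, pi / 2)
  r <- ifelse(cap, radius * sin(s / radius), radius)
  z <- ifelse(cap, -radius * (1 - cos(s / radius)), -radius - (s - s_cap))
  ks <- ifelse(cap, 1 / radius, 0)
  kt <- ifelse(s > 1e-9, sin(phi) / pmax(r, 1e-300), 1 / radius)
  meridian_contour(s, phi, r, z, ks, kt)
}

#' Pointy (non-hemispherical) cap family
#'
#' Generates a family of pointed end shapes by letting the meridional
#' curvature decay as `kappa_s(s) = k0 * exp(-(s/w)^p)` and scaling the
#' whole curve so the flank radius equals `radius`. `k0` is chosen so the
#' normal angle reaches pi/2 (the flank is a proper cylinder). Larger `p`
#' with small `w` concentrates curvature at the pole, giving pointier ends.
#'
#' @param radius target flank radius (um).
#' @param w decay length of the curvature tail, in units of the (unscaled)
#'   arclength; controls how far curvature extends from the pole.
#' @param p decay exponent (> 0).
#' @param flank flank length (um) appended after the curved zone.
#' @param n grid points.
#' @return A [meridian_contour()].
#' @export
pointy_cap_meridian <- function(radius, w = 1, p = 2, flank = 2 * radius,
                                n = 241) {
  stopifnot(radius > 0, w > 0, p > 0)
  # unit-family: curvature k0*exp(-(s/w)^p) on [0, s_cap], k0 s.t. phi->pi/2
  s_cap <- w * (log(1e6))^(1 / p)  # where the tail is numerically dead
  su <- seq(0, s_cap, length.out = 2001)
  shape <- exp(-(su / w)^p)
  k0 <- (pi / 2) / as.numeric(utils::tail(pracma::cumtrapz(su, shape), 1))
  phi <- pmin(as.numeric(pracma::cumtrapz(su, k0 * shape)), pi / 2)
  r_end <- utils::tail(as.numeric(pracma::cumtrapz(su, cos(phi))), 1)
  sc <- radius / r_end                      # uniform length rescale
  s_tot <- s_cap * sc + flank
  s <- seq(0, s_tot, length.out = n)
  ks <- ifelse(s <= s_cap * sc, (k0 / sc) * exp(-(s / (w * sc))^p), 0)
  reconstruct_meridian(ks, s)
}

#' Interpolate the normal angle of a meridian at arbitrary arclength
#' @param meridian a [meridian_contour()].
#' @return a function `phi(s)`.
#' @export
phi_of_s <- function(meridian) {
  stats::approxfun(meridian$s, meridian$phi, rule = 2)
}

#' @export
print.meridian_contour <- function(x, ...) {
  cat(sprintf(
    "meridian_contour: %d points, s in [0, %.3g] um, flank radius %.3g um\n",
    nrow(x), max(x$s), x$r[nrow(x)]))
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

# discrete meridian measures from nodal (r, z): arclength, segment angles,
# nodal turning-angle curvature. Used by the shell solver and by
# meridian_from_rz().
.polyline_measures <- function(r, z) {
  dr <- diff(r); dz <- diff(z)
  ds <- sqrt(dr^2 + dz^2)
  theta <- atan2(dz, dr)                 # segment direction angle
  n <- length(r)
  s <- c(0, cumsum(ds))
  # turning angle at interior nodes, wrapped to (-pi, pi)
  dth <- diff(theta)
  dth <- atan2(sin(dth), cos(dth))
  ell <- (ds[-length(ds)] + ds[-1]) / 2
  kappa_node <- c(NA_real_, -dth / ell, NA_real_)  # sign: convex outward > 0
  list(s = s, ds = ds, theta = theta, kappa_node = kappa_node)
}

# Build a meridian_contour from half-profile nodes (r, z) starting at the
# pole (r[1] ~ 0). Curvature from turning angles, endpoints extrapolated.
meridian_from_rz <- function(r, z) {
  pm <- .polyline_measures(r, z)
  n <- length(r)
  ks <- pm$kappa_node
  ks[1] <- ks[2]; ks[n] <- ks[n - 1]
  # phi from segment angles: outward normal angle = -theta for our
  # orientation (z decreasing away from pole, r increasing)
  phi_seg <- -pm$theta
  phi <- c(0, (phi_seg[-length(phi_seg)] + phi_seg[-1]) / 2, phi_seg[length(phi_seg)])
  phi[n] <- phi_seg[length(phi_seg)]
  kt <- ifelse(r > 1e-9, sin(phi) / pmax(r, 1e-300), ks)
  r0 <- r - r[1]
  meridian_contour(pm$s, phi, r0, z - z[1], ks, kt)
}
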