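#' Elastic material parameters of the cell wall
#'
#' The wall is characterized by two dimensionless numbers: the Young's
#' modulus normalized by turgor pressure (`E_over_P`) and the Poisson
#' ratio `nu`. Near-zero and slightly negative `nu` are admissible (2-D
#' fibre networks under tension can show such values). A third
#' configuration constant, `thickness_to_radius`, converts the normalized
#' modulus into a membrane stiffness; it is not measurable from contour
#' data alone (E/P and t enter only through their product) and defaults to
#' 0.0974, the value back-computed so that the classic plasmolysis strains
#' (0.13 meridional, 0.24 circumferential) map to E/P = 44 in the
#' thin-cylinder estimator.
#'
#' @param E_over_P normalized Young's modulus (> 0).
#' @param nu Poisson ratio, in (-1, 0.5).
#' @param thickness_to_radius wall thickness / cell radius.
#' @return An object of class `elastic_params`.
#' @export
elastic_params <- function(E_over_P, nu, thickness_to_radius = 0.0974) {
  stopifnot(E_over_P > 0, thickness_to_radius > 0)
  if (nu <= -1 || nu >= 0.5)
    stop("nu must lie in (-1, 0.5)")
  structure(list(E_over_P = E_over_P, nu = nu,
                 thickness_to_radius = thickness_to_radius),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf("elastic_params: E/P = %.4g, nu = %.4g (t/R = %.4g)\n",
              x$E_over_P, x$nu, x$thickness_to_radius))
  invisible(x)
}

#' Thin-cylinder estimator of wall elastic properties
#'
#' In a cylindrical pressure vessel the circumferential stress is twice
#' the meridional stress, so the plasmolysis strains on the cell cylinder
#' determine the Poisson ratio through
#' `nu = (0.5 * rho - 1) / (rho - 0.5)`, with
#' `rho = eps_circumferential / eps_meridional`. The normalized modulus
#' follows from the circumferential closed form
#' `eps_theta = (P R / E t) (1 - nu/2)`.
#'
#' @param eps_meridional meridional elastic strain (> 0), e.g. from Qdot
#'   pair distances before/after plasmolysis.
#' @param eps_circumferential circumferential elastic strain (> 0), e.g.
#'   from cell width change.
#' @param thickness_to_radius wall thickness over radius (see
#'   [elastic_params()]).
#' @return An [elastic_params()] with attribute `rho`.
#' @examples
#' cylinder_estimator(0.13, 0.24)   # nu ~ -0.06, E/P ~ 44
#' @export
cylinder_estimator <- function(eps_meridional, eps_circumferential,
                               thickness_to_radius = 0.0974) {
  stopifnot(eps_meridional > 0, eps_circumferential > 0)
  rho <- eps_circumferential / eps_meridional
  if (rho <= 0.5)
    stop("strain ratio <= 0.5: outside the thin-cylinder regime")
  nu <- (0.5 * rho - 1) / (rho - 0.5)
  if (nu <= -1 + 1e-12)
    stop("strain ratio 1 implies nu = -1: boundary of admissible range")
  E_over_P <- (1 / thickness_to_radius) * (1 - nu / 2) / eps_circumferential
  out <- elastic_params(E_over_P, nu, thickness_to_radius)
  attr(out, "rho") <- rho
  out
}

#' Inflate an axisymmetric shell under turgor pressure
#'
#' Computes the static equilibrium of a thin elastic shell whose resting
#' (stress-free) meridian is given, under uniform internal pressure, by
#' total-potential-energy minimization (see the package vignette for the
#' discretization). The `membrane` model is appropriate for slender,
#' smooth resting shapes; `bending_shear` adds plate-like bending
#' stiffness and is needed for high-curvature resting shapes.
#'
#' @param resting a [meridian_contour()] for the stress-free half-cell
#'   (pole to symmetry plane) or cap.
#' @param params an [elastic_params()].
#' @param pressure normalized pressure (units of turgor P; default 1).
#' @param model `"membrane"` or `"bending_shear"`.
#' @param bc `"symmetry"` (far end on the mid-plane: axial position fixed,
#'   radius free) or `"clamped"` (both fixed; e.g. septum junction).
#' @param init optional list(r, z) warm start.
#' @return An object of class `shell_solution`: list with `resting`,
#'   `deformed` (both [meridian_contour()]s), `lambda_s`, `lambda_theta`
#'   (per-element stretches), `model`, `residual`, `converged`,
#'   `r`, `z` (deformed nodes).
#' @export
inflate_shell <- function(resting, params, pressure = 1,
                          model = c("membrane", "bending_shear"),
                          bc = c("symmetry", "clamped"), init = NULL) {
  model <- match.arg(model); bc <- match.arg(bc)
  stopifnot(inherits(resting, "meridian_contour"),
            inherits(params, "elastic_params"))
  sp <- .shell_spec(resting$r, resting$z, params, pressure, model, bc)
  if (pressure == 0) {
    sol <- list(r = resting$r, z = resting$z, residual = 0, converged = TRUE,
                residual_history = 0)
  } else {
    r0 <- if (is.null(init)) resting$r else init$r
    z0 <- if (is.null(init)) resting$z else init$z
    sol <- .shell_solve(sp, r0, z0)
  }
  ds <- sqrt(diff(sol$r)^2 + diff(sol$z)^2)
  structure(list(resting = resting,
                 deformed = meridian_from_rz(sol$r, sol$z),
                 r = sol$r, z = sol$z,
                 lambda_s = ds / sp$ds0,
                 lambda_theta = (sol$r[-1] + sol$r[-length(sol$r)]) / 2 / sp$rb0,
                 model = model, residual = sol$residual,
                 converged = sol$converged),
            class = "shell_solution")
}

#' @export
print.shell_solution <- function(x, ...) {
  cat(sprintf(
    "shell_solution (%s): max stretch s %.3f / theta %.3f, residual %.2g\n",
    x$model, max(x$lambda_s), max(x$lambda_theta), x$residual))
  invisible(x)
}

# ---- outline symmetrization -----------------------------------------------

#' Symmetrize a closed cell outline into a half meridian
#'
#' Rotates the outline onto its principal axis, folds the two sides of the
#' axis together (averaging the half-widths at matched axial positions)
#' and returns the half meridian from the chosen end pole to the cell
#' mid-plane, resampled at uniform arclength. This is the standard
#' preparation step before elastic-shell fitting of plasmolysis data.
#'
#' @param outline data frame with columns `x`, `y` (um) tracing a closed
#'   cell contour, or a [planar_outline()] (pixels are converted).
#' @param n number of nodes of the returned half meridian.
#' @param end which cell end to use as the pole: `"right"` (larger axis
#'   coordinate) or `"left"`.
#' @param smooth_um width (um) of the periodic Gaussian kernel used to
#'   smooth the contour along its arclength before symmetrization; 0
#'   disables smoothing.
#' @return A [meridian_contour()] from the pole to the mid-plane.
#' @export
symmetrize_outline <- function(outline, n = 61, end = c("right", "left"),
                               smooth_um = 0.25) {
  end <- match.arg(end)
  x <- outline$x; y <- outline$y
  if (inherits(outline, "planar_outline")) {
    px <- attr(outline, "pixel_size"); x <- x * px; y <- y * px
  }
  ctr <- c(mean(x), mean(y))
  pc <- stats::prcomp(cbind(x - ctr[1], y - ctr[2]))
  u <- cbind(x - ctr[1], y - ctr[2]) %*% pc$rotation
  ax <- u[, 1]; rad <- u[, 2]
  if (end == "left") ax <- -ax
  # smooth the closed contour with a periodic Gaussian kernel along the
  # chord-length parametrization (the tip stays well conditioned because
  # nothing is parametrized by the axial coordinate)
  tt <- c(0, cumsum(sqrt(diff(c(ax, ax[1]))^2 + diff(c(rad, rad[1]))^2)))
  L <- tt[length(tt)]
  tq <- tt[-length(tt)]
  if (smooth_um > 0) {
    sm <- function(vv) {
      out <- numeric(length(tq))
      for (i in seq_along(tq)) {
        d <- abs(tq - tq[i]); d <- pmin(d, L - d)
        w <- exp(-d^2 / (2 * smooth_um^2))
        out[i] <- sum(w * vv) / sum(w)
      }
      out
    }
    ax <- sm(ax); rad <- sm(rad)
  }
  # tip = extreme point along the axis; walk both arms toward the
  # mid-plane and average them at matched normalized arclength
  i_tip <- which.max(ax)
  m <- length(ax)
  ord1 <- ((i_tip - 1 + seq_len(m)) - 1) %% m + 1      # forward arm
  ord2 <- ((i_tip - 1 - seq_len(m)) + 2 * m) %% m + 1  # backward arm
  take_arm <- function(ord) {
    axa <- ax[ord]; ra <- rad[ord]
    stopi <- which(axa <= 0)[1]            # reach the mid-plane
    if (is.na(stopi)) stopi <- length(ord)
    idx <- seq_len(stopi)
    seg <- sqrt(diff(axa[idx])^2 + diff(ra[idx])^2)
    list(s = c(0, cumsum(seg)), ax = axa[idx], r = abs(ra[idx]))
  }
  a1 <- take_arm(ord1); a2 <- take_arm(ord2)
  fq <- seq(0, 1, length.out = n)
  r1 <- stats::approx(a1$s / max(a1$s), a1$r, xout = fq)$y
  z1 <- stats::approx(a1$s / max(a1$s), a1$ax, xout = fq)$y
  r2 <- stats::approx(a2$s / max(a2$s), a2$r, xout = fq)$y
  z2 <- stats::approx(a2$s / max(a2$s), a2$ax, xout = fq)$y
  r_half <- (r1 + r2) / 2
  z_half <- (z1 + z2) / 2 - (z1[1] + z2[1]) / 2   # 0 at the tip
  r_half[1] <- 0
  meridian_from_rz(r_half, z_half)
}

#' Fit elastic parameters from a plasmolysed/turgid contour pair
#'
#' Follows the three-step estimation used on plasmolysis experiments:
#' extract/symmetrize the two contours, numerically inflate the
#' plasmolysed (assumed stress-free) shape for candidate values of
#' (E/P, nu), and retain the values whose inflated shape best fits the
#' turgid contour. The mismatch is the RMS distance between the two
#' meridians sampled at matched normalized arclength.
#'
#' @param plasmolysed,turgid closed outlines (data frames `x`, `y`, um) or
#'   [meridian_contour()]s (already symmetrized half meridians).
#' @param thickness_to_radius see [elastic_params()].
#' @param model shell model passed to [inflate_shell()].
#' @param EP_range,nu_range search bounds.
#' @param grid_n coarse grid resolution per axis.
#' @param n_nodes meridian resampling for the solver.
#' @return An [elastic_params()] with attributes `residual` (um RMS),
#'   `at_bounds` (logical flag) and `fit` (data frame of the coarse grid).
#' @export
fit_elastic_params <- function(plasmolysed, turgid,
                               thickness_to_radius = 0.0974,
                               model = "membrane",
                               EP_range = c(15, 150), nu_range = c(-0.4, 0.45),
                               grid_n = 5, n_nodes = 41) {
  as_half <- function(o) {
    if (inherits(o, "meridian_contour")) o else symmetrize_outline(o, n = n_nodes)
  }
  rest <- as_half(plasmolysed)
  targ <- as_half(turgid)
  # resample both to n_nodes by arclength
  resamp <- function(m, n) {
    sq <- seq(0, max(m$s), length.out = n)
    r <- stats::approx(m$s, m$r, xout = sq)$y
    z <- stats::approx(m$s, m$z, xout = sq)$y
    r[1] <- 0
    meridian_from_rz(r, z)
  }
  rest <- resamp(rest, n_nodes)
  targ <- resamp(targ, n_nodes)
  tq <- seq(0, 1, length.out = 81)
  targ_r <- stats::approx(targ$s / max(targ$s), targ$r, xout = tq)$y
  targ_z <- stats::approx(targ$s / max(targ$s), targ$z, xout = tq)$y
  warm <- new.env()
  warm$init <- NULL
  mism <- function(lep, nu) {
    p <- elastic_params(exp(lep), nu, thickness_to_radius)
    sol <- tryCatch(
      inflate_shell(rest, p, pressure = 1, model = model, init = warm$init),
      error = function(e) NULL)
    if (is.null(sol)) return(1e6)
    warm$init <- list(r = sol$r, z = sol$z)
    d <- sol$deformed
    dr <- stats::approx(d$s / max(d$s), d$r, xout = tq)$y
    dz <- stats::approx(d$s / max(d$s), d$z, xout = tq)$y
    sqrt(mean((dr - targ_r)^2 + (dz - targ_z)^2))
  }
  eps <- seq(log(EP_range[1]), log(EP_range[2]), length.out = grid_n)
  nus <- seq(nu_range[1], nu_range[2], length.out = grid_n)
  grid <- expand.grid(lep = eps, nu = nus)
  grid$score <- mapply(mism, grid$lep, grid$nu)
  best <- grid[which.min(grid$score), ]
  opt <- stats::optim(c(best$lep, best$nu),
                      function(p) {
                        if (p[2] <= -0.9 || p[2] >= 0.49) return(1e6)
                        mism(p[1], p[2])
                      },
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  at_bounds <- opt$par[1] <= log(EP_range[1]) + 1e-3 ||
    opt$par[1] >= log(EP_range[2]) - 1e-3 ||
    opt$par[2] <= nu_range[1] + 1e-3 || opt$par[2] >= nu_range[2] - 1e-3
  if (at_bounds) warning("optimizer at parameter bounds; fit unreliable")
  res <- elastic_params(exp(opt$par[1]), opt$par[2], thickness_to_radius)
  if (opt$value > 0.02 * max(rest$r))
    warning(sprintf(
      "large contour mismatch (%.3g um): outlines may not form a valid pair",
      opt$value))
  attr(res, "residual") <- opt$value
  attr(res, "at_bounds") <- at_bounds
  attr(res, "fit") <- data.frame(E_over_P = exp(grid$lep), nu = grid$nu,
                                 score = grid$score)
  res
}

#' Inflate the division septum into a new end
#'
#' The septum forms as a flat disc inside the mother's load-bearing wall
#' and only deforms after cell separation. Its stress-free meridional
#' length is unknown but exceeds the septum radius; it is parameterized
#' here by `resting_length_factor` (resting meridional length / septum
#' radius). The resting shape is the spherical cap whose base radius is
#' the septum radius and whose arc length matches the resting length
#' (exactly flat for factor 1); it is clamped at the old-wall junction and
#' inflated with the bending shell model. The deformed cap shows the
#' division-scar curvature ridge at the junction.
#'
#' @param septum_radius um.
#' @param resting_length_factor >= 1 (1.3 reproduces the near-hemispherical
#'   new-end transition).
#' @param params an [elastic_params()].
#' @param pressure normalized pressure.
#' @param n nodes along the septum meridian.
#' @return A list with `meridian` (deformed cap, pole first),
#'   `pole_deflection` (um, axial bulge of the pole above the junction
#'   plane), `pole_curvature` (1/um), `kappa_profile` (data frame) and the
#'   underlying `solution`.
#' @export
inflate_septum <- function(septum_radius, resting_length_factor,
                           params, pressure = 1, n = 61) {
  stopifnot(septum_radius > 0)
  if (resting_length_factor < 1)
    stop("resting_length_factor must be >= 1")
  L0 <- resting_length_factor * septum_radius
  # spherical-cap resting shape: arc length L0, base radius septum_radius
  if (resting_length_factor > 1 + 1e-9) {
    f <- function(x) sin(x) / x - septum_radius / L0
    x <- stats::uniroot(f, c(1e-6, pi - 1e-6))$root
    kap <- x / L0
    s <- seq(0, L0, length.out = n)
    r0 <- sin(kap * s) / kap
    z0 <- (cos(kap * s) - 1) / kap   # pole at z=0, edge below
    # shift so the clamped edge sits at z = 0
    z0 <- z0 - z0[n]
  } else {
    s <- seq(0, L0, length.out = n)
    r0 <- s
    z0 <- rep(0, n)
  }
  sp_params <- params
  sp <- .shell_spec(r0, z0, sp_params, pressure, "bending_shear", "clamped",
                    stiffness_radius = septum_radius)
  # bias the initial guess outward so inflation picks the bulge direction
  z_init <- z0 + 0.05 * septum_radius * cos(pi * r0 / (2 * septum_radius))
  sol <- .shell_solve(sp, r0, z_init)
  m <- meridian_from_rz(sol$r, sol$z)
  kp <- data.frame(s_um = m$s, kappa_s = m$kappa_s)
  list(meridian = m,
       pole_deflection = sol$z[1] - sol$z[n],
       pole_curvature = m$kappa_s[1],
       kappa_profile = kp,
       solution = sol)
}
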