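#' Extract a cortical fluorescence profile along a cell outline
#'
#' For every position along the (resampled) outline, integrates the pixel
#' intensity within a narrow window of half-width `h` centred on the
#' contour and orthogonal to it. Positions are reported as meridional
#' distance from a pole anchor.
#'
#' @param img image matrix (rows = y, cols = x).
#' @param outline a [planar_outline()].
#' @param h window half-width (um).
#' @param pole_index index (into the resampled outline) of the pole; the
#'   profile's `s_um = 0` is placed there. Default: point of maximal
#'   image x (right-most), a convenience for synthetic rod cells.
#' @param spacing contour resampling spacing (px).
#' @return data frame with `s_um` (signed meridional distance from the
#'   pole along the contour) and `intensity`.
#' @export
extract_profile <- function(img, outline, h = 0.3, pole_index = NULL,
                            spacing = 1) {
  px <- attr(outline, "pixel_size")
  res <- resample_outline(outline, spacing = spacing)
  n <- nrow(res)
  x <- res$x; y <- res$y
  tx <- (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / 2
  ty <- (y[c(2:n, 1)] - y[c(n, 1:(n - 1))]) / 2
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  h_px <- h / px
  offs <- seq(-h_px, h_px, length.out = max(5L, 2L * ceiling(h_px) + 1L))
  inten <- numeric(n)
  nr <- nrow(img); nc <- ncol(img)
  truncated <- FALSE
  for (i in seq_len(n)) {
    qx <- x[i] + offs * nx[i]
    qy <- y[i] + offs * ny[i]
    ok <- qx >= 0 & qx <= nc - 1 & qy >= 0 & qy <= nr - 1
    if (!all(ok)) truncated <- TRUE
    inten[i] <- sum(.bilinear(img, qx[ok], qy[ok])) *
      (offs[2] - offs[1]) * px
  }
  if (truncated) warning("window exits the image; profile truncated there")
  if (is.null(pole_index)) pole_index <- which.max(x)
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2) * px
  s <- c(0, cumsum(seg))[seq_len(n)]
  s_rel <- s - s[pole_index]
  # wrap to (-L/2, L/2] so the pole is central
  L <- sum(seg)
  s_rel <- ifelse(s_rel > L / 2, s_rel - L, ifelse(s_rel <= -L / 2,
                                                   s_rel + L, s_rel))
  out <- data.frame(s_um = s_rel, intensity = inten)
  out[order(out$s_um), ]
}

#' Curvature-area correction of a cortical profile
#'
#' The wall area seen by a window of half-width `h` at a point with
#' circumferential curvature radius `R_theta` is `ds * sqrt(2 h R_theta)`,
#' so recorded intensities are divided by that area element to yield a
#' per-area density. Since `R_theta` varies modestly along a cell end and
#' enters as a square root, the correction is small.
#'
#' @param profile data frame `s_um`, `intensity` (positions >= 0 matched
#'   to the meridian by arclength).
#' @param meridian a [meridian_contour()] supplying `kappa_theta`.
#' @param h window half-width (um).
#' @return The profile with `intensity` replaced by the per-area density
#'   (arbitrary units) and an extra column `area_element`.
#' @export
area_correct <- function(profile, meridian, h = 0.3) {
  kt <- stats::approx(meridian$s, meridian$kappa_theta,
                      xout = pmin(abs(profile$s_um), max(meridian$s)),
                      rule = 2)$y
  if (any(kt <= 0)) stop("non-positive circumferential curvature")
  ds <- stats::median(abs(diff(profile$s_um)))
  area <- ds * sqrt(2 * h / kt)
  out <- profile
  out$intensity <- profile$intensity / area
  out$area_element <- area
  out
}

# map the csaps-style smoothing parameter p in [0, 1) to the lambda of
# stats::smooth.spline (whose penalty is on the unit-scaled abscissa)
.csaps_lambda <- function(p, x) {
  (1 - p) / p / diff(range(x))^3
}

#' Condition raw fluorescence frames into a normalized profile
#'
#' Frames are averaged, fitted with a weak cubic smoothing spline
#' (parameter 0.8 in the `p`-convention where 1 means interpolation), the
#' spline minimum is subtracted as background, the peak is scaled to 1
#' and (optionally) the profile is symmetrized about the pole.
#'
#' @param frames matrix (n_frames x n_s) of raw intensities, or a list
#'   with `frames` and `s_um` as produced by
#'   [synth_fluorescence_profiles()].
#' @param s_um grid (required if `frames` is a matrix).
#' @param p smoothing parameter in (0, 1]; 0.8 is weak smoothing.
#' @param symmetrize average `gamma(s)` and `gamma(-s)`.
#' @return An object of class `fluorescence_profile`: data frame `s_um`,
#'   `gamma` (in [0, 1]), `sd` (per-point frame sd, same conditioning
#'   scale), with attributes `n_frames` and `p`.
#' @export
condition_profile <- function(frames, s_um = NULL, p = 0.8,
                              symmetrize = TRUE) {
  if (is.list(frames) && !is.matrix(frames)) {
    s_um <- frames$s_um
    frames <- frames$frames
  }
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1)
  stopifnot(!is.null(s_um), ncol(frames) == length(s_um))
  avg <- colMeans(frames)
  if (max(avg) - min(avg) < 1e-12)
    stop("flat profile: normalization undefined")
  fit <- stats::smooth.spline(s_um, avg, lambda = .csaps_lambda(p, s_um))
  g <- stats::predict(fit, s_um)$y
  bg <- min(g)
  g <- g - bg
  pk <- max(g)
  g <- g / pk
  sdv <- if (nrow(frames) > 1) apply(frames, 2, stats::sd) / pk
  else rep(0, length(s_um))
  if (symmetrize) {
    gm <- stats::approx(-s_um, g, xout = s_um, rule = 2)$y
    g <- (g + gm) / 2
    # renormalize after symmetrization
    g <- (g - min(g)) / (max(g) - min(g))
  }
  g <- pmin(pmax(g, 0), 1)
  out <- data.frame(s_um = s_um, gamma = g, sd = sdv)
  class(out) <- c("fluorescence_profile", "data.frame")
  attr(out, "n_frames") <- nrow(frames)
  attr(out, "p") <- p
  out
}

#' Central-area width of a profile (FWHA / FW95A)
#'
#' Width of the central interval that contains the given `fraction` of the
#' total area under the profile, positioned so that the two lateral areas
#' are equal. `fraction = 0.5` is the full-width at half area (FWHA),
#' `fraction = 0.95` the full-width at 95% area (FW95A). The interval is
#' found by inverting the cumulative area (linear interpolation between
#' grid points).
#'
#' @param profile data frame with `s_um` and `gamma` (or `intensity`).
#' @param fraction central area fraction in (0, 1).
#' @return Width in um.
#' @examples
#' s <- seq(-6, 6, length.out = 1001)
#' g <- exp(-s^2 / 2)
#' central_width(data.frame(s_um = s, gamma = g), 0.5)   # ~1.349 sigma
#' @export
central_width <- function(profile, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  s <- profile$s_um
  y <- if ("gamma" %in% names(profile)) profile$gamma else profile$intensity
  if (any(y < -1e-9 * max(abs(y)))) y <- pmax(y, 0)
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(s)))
  tot <- cum[length(cum)]
  if (tot <= 0) stop("zero total area")
  q <- function(f) {
    target <- f * tot
    i <- findInterval(target, cum, all.inside = TRUE)
    s[i] + (target - cum[i]) / max(cum[i + 1] - cum[i], 1e-300) *
      (s[i + 1] - s[i])
  }
  lo <- (1 - fraction) / 2
  q(1 - lo) - q(lo)
}

#' Advection-incorporation distortion of a deposition profile
#'
#' Cortical markers are confined near the pole, but the wall material they
#' deposit flows with the expanding wall. With deposition following
#' `gamma(s)^alpha` (a one-parameter nonlinearity), incorporation into the
#' load-bearing wall at rate `k`, dilution by the areal expansion `A(s)`
#' and meridional advection at the wall velocity `v(s)`, the steady-state
#' concentration of free material obeys
#' `v dchi/ds = gamma^alpha - (k + A) chi`.
#' The solution is computed twice: by direct ODE integration and by the
#' closed-form transit-time integral
#' `chi(s) = (v r)^-1 int_0^s gamma^alpha r exp(-k (tau(s) - tau(xi))) dxi`
#' with `tau` the transit time; the two must agree.
#' As `k` grows, `chi` approaches `gamma^alpha` (fast incorporation:
#' no smearing); small `k` smears the profile down the flank.
#'
#' @param gamma_profile data frame `s_um` (>= 0), `gamma`.
#' @param velocity a [velocity_profile()].
#' @param meridian a [meridian_contour()] (supplies `phi(s)`, `r(s)`).
#' @param k incorporation rate (per unit transit time, >= 0).
#' @param deposition_exponent nonlinearity exponent alpha (> 0).
#' @param s0 inner offset from the pole (the pole is a logarithmic
#'   singularity of the transit time).
#' @return data frame `s_um`, `chi_ode`, `chi_closed` (both normalized to
#'   peak 1), with attribute `max_rel_diff` (their maximum relative
#'   disagreement on the common grid).
#' @export
advect_profile <- function(gamma_profile, velocity, meridian, k,
                           deposition_exponent = 1, s0 = NULL) {
  stopifnot(k >= 0, deposition_exponent > 0)
  m <- meridian
  s_max <- max(m$s)
  half <- gamma_profile[gamma_profile$s_um >= 0, ]
  gf <- stats::approxfun(half$s_um, half$gamma^deposition_exponent,
                         yright = 0, rule = 2)
  vf <- function(s) vp_eval(velocity, phi_of_s(m)(s))
  rf <- stats::approxfun(m$s, pmax(m$r, 1e-9), rule = 2)
  sgrid <- m$s[m$s > 0]
  v_g <- vf(sgrid)
  if (any(v_g <= 0)) stop("velocity must be positive away from the pole")
  if (is.null(s0)) s0 <- max(s_max / 400, sgrid[1])
  # --- ODE route, conservation form: with y = v r chi the same equation
  # reads dy/ds = gamma^alpha r - k y / v, which eliminates the
  # numerically differentiated areal-strain term.
  # Regular series start: chi(0) = gamma^alpha(0) / (k + A(0)) with
  # A(0) = 2 v'(0) at the pole.
  h <- s0 / 10
  vp0 <- (vf(h) - vf(h / 2)) / (h / 2)      # v'(0)
  chi0 <- gf(0) / (k + 2 * vp0)
  rhs <- function(s, y, parms) list(gf(s) * rf(s) - k * y[1] / vf(s))
  sq <- seq(s0, s_max, length.out = 200)
  s_start <- s0 / 20   # series start error is O(s_start^2)
  ode <- deSolve::lsoda(y = c(y = chi0 * vf(s_start) * rf(s_start)),
                        times = c(s_start, sq), func = rhs,
                        rtol = 1e-10, atol = 1e-13)
  chi_ode <- ode[-1, 2] / (vf(sq) * rf(sq))
  # --- closed form via transit time, integrated in tau with an
  # exponential-exact rule (linear prefactor x exponential per interval,
  # robust for large k where the kernel is a boundary layer).
  # log-spaced abscissae give near-constant transit-time spacing close to
  # the pole, where tau ~ log(s)
  fine <- unique(sort(c(exp(seq(log(s0 / 1000), log(s_max),
                                length.out = 4000)), sq)))
  tau <- as.numeric(pracma::cumtrapz(fine, 1 / vf(fine)))
  gfr <- gf(fine) * rf(fine) * vf(fine)   # Jacobian: dxi = v dtau
  # cumulative integral J(s) = int exp(k tau(xi)) g r dxi evaluated
  # stably: work per output point with shifted exponents
  chi_cl <- numeric(length(sq))
  ii <- match(sq, fine)
  for (jj in seq_along(sq)) {
    iN <- ii[jj]
    Tj <- tau[iN]
    idx <- seq_len(iN - 1)
    ta <- tau[idx]; tb <- tau[idx + 1]
    ga <- gfr[idx]; gb <- gfr[idx + 1]
    dt <- tb - ta
    ea <- exp(-k * (Tj - ta)); eb <- exp(-k * (Tj - tb))
    if (k > 0) {
      # int_{ta}^{tb} (ga + (gb-ga)(t-ta)/dt) e^{-k(Tj-t)} dt
      base <- ga * (eb - ea) / k
      slope <- (gb - ga) / dt * (dt * eb / k - (eb - ea) / k^2)
      contrib <- base + slope
    } else {
      contrib <- (ga + gb) / 2 * dt
    }
    chi_cl[jj] <- sum(contrib) / (vf(sq[jj]) * rf(sq[jj]))
  }
  scale <- max(chi_ode)
  out <- data.frame(s_um = sq, chi_ode = chi_ode / scale,
                    chi_closed = chi_cl / scale)
  attr(out, "max_rel_diff") <- max(abs(chi_ode - chi_cl)) / scale
  attr(out, "k") <- k
  attr(out, "deposition_exponent") <- deposition_exponent
  out
}

#' Compare and cluster marker distributions
#'
#' Builds a feature vector per marker -- either the pair (FWHA, FW95A) or
#' a sampled predicted end-shape curvature from the growth model -- and
#' clusters markers by euclidean distance and agglomerative linkage.
#'
#' @param profiles named list of conditioned profiles (data frames
#'   `s_um`, `gamma`).
#' @param metric `"width_features"` or `"predicted_curvature"`.
#' @param linkage linkage method (`"single"`, `"average"`, `"complete"`).
#' @param params elastic parameters for the `predicted_curvature` metric.
#' @param shape_args extra arguments to [marker_driven_shape()].
#' @param kappa_s_grid sampling grid for predicted curvature features.
#' @return An object of class `marker_dendrogram`: list with `labels`,
#'   `dist` (matrix), `hclust`, `newick` (string), `features`.
#' @export
compare_and_cluster_markers <- function(profiles,
                                        metric = c("width_features",
                                                   "predicted_curvature"),
                                        linkage = c("single", "average",
                                                    "complete"),
                                        params = elastic_params(40, 0.3),
                                        shape_args = list(),
                                        kappa_s_grid = seq(0, 3, by = 0.5)) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  stopifnot(length(profiles) >= 2, !is.null(names(profiles)))
  feats <- list()
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    f <- if (metric == "width_features") {
      c(FWHA = central_width(pr, 0.5), FW95A = central_width(pr, 0.95))
    } else {
      sh <- tryCatch(
        do.call(marker_driven_shape,
                c(list(profile = pr, params = params), shape_args)),
        error = function(e) NULL)
      if (is.null(sh)) {
        warning(sprintf("shape prediction failed for '%s'; marker dropped", nm))
        NULL
      } else {
        stats::approx(sh$meridian$s, sh$meridian$kappa_s,
                      xout = kappa_s_grid, rule = 2)$y
      }
    }
    if (!is.null(f)) feats[[nm]] <- f
  }
  if (length(feats) < 2) stop("fewer than two markers with valid features")
  mat <- do.call(rbind, feats)
  d <- stats::dist(mat, method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(labels = rownames(mat), dist = as.matrix(d), hclust = hc,
                 newick = ape::write.tree(phy), features = mat,
                 metric = metric, linkage = linkage),
            class = "marker_dendrogram")
}

#' @export
print.marker_dendrogram <- function(x, ...) {
  cat(sprintf("marker_dendrogram (%s, %s linkage): %d markers\n%s\n",
              x$metric, x$linkage, length(x$labels), x$newick))
  invisible(x)
}

#' Ergodicity check: single-cell time series vs population widths
#'
#' Compares the distribution of FWHA values obtained by following one cell
#' over time against the distribution over a population, with a two-sample
#' Kolmogorov-Smirnov test. Under ergodicity the two coincide.
#'
#' @param single_cell_widths numeric vector of per-frame FWHA values for
#'   one cell (um).
#' @param population_widths numeric vector of per-cell FWHA values (um).
#' @param level flag threshold for the p-value.
#' @return list with `statistic`, `p_value`, `flagged` (TRUE when the
#'   distributions differ at `level`), and the two sample summaries.
#' @export
ergodicity_check <- function(single_cell_widths, population_widths,
                             level = 0.05) {
  stopifnot(length(single_cell_widths) >= 1, length(population_widths) >= 1)
  if (identical(single_cell_widths, population_widths)) {
    ks <- list(statistic = c(D = 0), p.value = 1)
  } else {
    ks <- suppressWarnings(stats::ks.test(single_cell_widths,
                                          population_widths))
  }
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       flagged = ks$p.value < level,
       single = summary(single_cell_widths),
       population = summary(population_widths))
}

#' FWHA versus cell width across genotypes
#'
#' Summarizes per-genotype marker FWHA against cell width and fits the
#' linear trend, optionally comparing with a reference relationship (the
#' wild-type expansion-width line).
#'
#' @param data data frame with columns `genotype`, `fwha`, `width` (um).
#' @param reference optional function width -> FWHA for the reference
#'   line.
#' @return list with `groups` (per-genotype mean and sd), `slope`,
#'   `slope_ci` (95%), `fit` (the lm object) and, when a reference is
#'   given, `reference_delta` per genotype.
#' @export
fwha_vs_width <- function(data, reference = NULL) {
  stopifnot(all(c("genotype", "fwha", "width") %in% names(data)))
  groups <- do.call(rbind, lapply(split(data, data$genotype), function(d)
    data.frame(genotype = d$genotype[1],
               width_mean = mean(d$width), width_sd = stats::sd(d$width),
               fwha_mean = mean(d$fwha), fwha_sd = stats::sd(d$fwha),
               n = nrow(d))))
  rownames(groups) <- NULL
  if (length(unique(data$genotype)) < 2) {
    return(list(groups = groups, slope = NA_real_,
                slope_ci = c(NA_real_, NA_real_), fit = NULL,
                note = "single group: slope undefined"))
  }
  fit <- stats::lm(fwha ~ width, data = data)
  ci <- stats::confint(fit)["width", ]
  out <- list(groups = groups,
              slope = unname(stats::coef(fit)["width"]),
              slope_ci = unname(ci), fit = fit)
  if (!is.null(reference)) {
    groups$reference_fwha <- reference(groups$width_mean)
    out$reference_delta <- groups$fwha_mean - groups$reference_fwha
    out$groups <- groups
  }
  out
}
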