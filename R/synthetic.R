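#' Synthetic-data scenario
#'
#' Bundles the parameters that determine every synthetic data set: the
#' random seed (all generators are deterministic given the seed), the
#' image scale, the cell geometry, the per-frame tip growth increments and
#' the output noise levels.
#'
#' Growth increments emulate the irregular growth spurts of real cells:
#' per-frame increments are `dh_mean` times i.i.d. lognormal multipliers
#' with log-sd `fluctuation` (mean multiplier 1). Increments are always
#' >= 0.
#'
#' @param seed integer seed.
#' @param pixel_size um per pixel.
#' @param cell_radius um (> 0).
#' @param end_shape list: `list(type = "hemisphere")` or
#'   `list(type = "pointy", w = ..., p = ...)` (see
#'   [pointy_cap_meridian()]).
#' @param n_frames number of frames.
#' @param dh_mean mean tip advance per frame (um, >= 0).
#' @param fluctuation lognormal log-sd of the growth multipliers.
#' @param noise_sd list of noise levels: `image` (intensity units),
#'   `track` (um), `profile` (intensity), `contour` (um).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, pixel_size = 0.067,
                               cell_radius = 2,
                               end_shape = list(type = "hemisphere"),
                               n_frames = 10L, dh_mean = 0.3,
                               fluctuation = 0,
                               noise_sd = list(image = 0, track = 0,
                                               profile = 0, contour = 0)) {
  stopifnot(cell_radius > 0, pixel_size > 0, n_frames >= 1, dh_mean >= 0,
            fluctuation >= 0)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 cell_radius = cell_radius, end_shape = end_shape,
                 n_frames = as.integer(n_frames), dh_mean = dh_mean,
                 fluctuation = fluctuation, noise_sd = noise_sd),
            class = "synthetic_scenario")
}

# growth increment series for a scenario (deterministic given seed)
.growth_series <- function(scenario) {
  set.seed(scenario$seed + 7L)
  n <- scenario$n_frames - 1L
  if (n <= 0) return(numeric(0))
  if (scenario$dh_mean == 0) return(rep(0, n))
  mult <- if (scenario$fluctuation > 0)
    exp(stats::rnorm(n, -scenario$fluctuation^2 / 2, scenario$fluctuation))
  else rep(1, n)
  scenario$dh_mean * mult
}

# meridian of the scenario end shape (pole first), with a long flank
.scenario_end_meridian <- function(scenario, flank = 3 * scenario$cell_radius,
                                   n = 241) {
  es <- scenario$end_shape
  if (identical(es$type, "hemisphere")) {
    cap_cylinder_meridian(scenario$cell_radius, flank = flank, n = n)
  } else if (identical(es$type, "pointy")) {
    pointy_cap_meridian(scenario$cell_radius,
                        w = if (is.null(es$w)) 1 else es$w,
                        p = if (is.null(es$p)) 2 else es$p,
                        flank = flank, n = n)
  } else stop("unknown end_shape type")
}

#' Synthetic bright-field-like image stack of a growing cell
#'
#' Renders, per frame, a closed high-contrast band at the ground-truth cell
#' outline of a rod-shaped cell whose right end advances according to the
#' scenario's growth series (the left end is a static hemisphere). Ground
#' truth outlines are returned alongside the images.
#'
#' @param scenario a [synthetic_scenario()].
#' @param body_length initial pole-to-pole length (um).
#' @param band_sd Gaussian width of the outline band (px).
#' @param contrast peak band intensity above background.
#' @return A list with `stack` (list of image matrices), `outlines`
#'   (list of ground-truth [planar_outline()]s in pixel coordinates) and
#'   `growth` (the per-frame tip advances, um).
#' @export
synth_cell_image_stack <- function(scenario, body_length = 7,
                                   band_sd = 1, contrast = 100) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  R <- scenario$cell_radius
  px <- scenario$pixel_size
  dh <- .growth_series(scenario)
  tip_adv <- c(0, cumsum(dh))
  m <- .scenario_end_meridian(scenario, flank = 0.5, n = 121)
  margin <- 1.5  # um around the cell
  W_um <- body_length + max(tip_adv) + 2 * margin
  H_um <- 2 * R + 2 * margin
  nc <- ceiling(W_um / px); nr <- ceiling(H_um / px)
  cy <- H_um / 2
  set.seed(scenario$seed + 13L)
  stack <- vector("list", scenario$n_frames)
  outlines <- vector("list", scenario$n_frames)
  # pixel center coordinates (um)
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  for (f in seq_len(scenario$n_frames)) {
    x_tip <- margin + body_length + tip_adv[f]
    # right cap from the end-shape meridian: pole at (x_tip, cy)
    cap_x <- x_tip + m$z          # z <= 0
    cap_y <- m$r
    keep <- cap_x >= margin + R   # stop where the body takes over
    cx <- cap_x[keep]; cyv <- cap_y[keep]
    x_join <- min(cx)
    # left static hemisphere
    th <- seq(pi / 2, 3 * pi / 2, length.out = 41)
    lx <- margin + R + R * cos(th); ly <- R * sin(th)
    # closed outline (um): tip -> top of right cap -> (straight top edge)
    # -> around the left cap -> (straight bottom edge) -> bottom of right
    # cap -> tip
    ox <- c(cx, lx, rev(cx))
    oy <- cy + c(cyv, ly, -rev(cyv))
    # thin out duplicate points (including the circular wrap)
    keep2 <- c(TRUE, sqrt(diff(ox)^2 + diff(oy)^2) > px / 4)
    ox <- ox[keep2]; oy <- oy[keep2]
    nn <- length(ox)
    if (sqrt((ox[nn] - ox[1])^2 + (oy[nn] - oy[1])^2) < px / 4) {
      ox <- ox[-nn]; oy <- oy[-nn]
    }
    # distance of every pixel to the outline polyline
    d2 <- matrix(Inf, nr, nc)
    n_seg <- length(ox)
    oxc <- c(ox, ox[1]); oyc <- c(oy, oy[1])
    PX <- matrix(xs, nr, nc, byrow = TRUE)
    PY <- matrix(ys, nr, nc)
    for (k in seq_len(n_seg)) {
      ax <- oxc[k]; ay <- oyc[k]; bx <- oxc[k + 1]; by <- oyc[k + 1]
      ex <- bx - ax; ey <- by - ay
      L2 <- ex^2 + ey^2
      if (L2 < 1e-12) next
      t <- pmin(pmax(((PX - ax) * ex + (PY - ay) * ey) / L2, 0), 1)
      dd <- (PX - (ax + t * ex))^2 + (PY - (ay + t * ey))^2
      d2 <- pmin(d2, dd)
    }
    img <- 10 + contrast * exp(-d2 / (2 * (band_sd * px)^2))
    if (scenario$noise_sd$image > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, scenario$noise_sd$image),
                          nr, nc)
    stack[[f]] <- img
    outlines[[f]] <- planar_outline(ox / px, oy / px, pixel_size = px,
                                    frame = f)
  }
  list(stack = stack, outlines = outlines, growth = dh)
}

#' Synthetic fiducial (Qdot) tracks advected by a velocity profile
#'
#' Seeds `n_tracks` fiducials on the growing end and advects them with the
#' prescribed meridional velocity field: per interval, the displacement is
#' `v(phi(s)) * dh` plus optional positional noise, with `dh` drawn from
#' the scenario's fluctuating growth series.
#'
#' @param velocity a [velocity_profile()].
#' @param meridian a [meridian_contour()] with a cylindrical flank (the
#'   equator, phi = pi/2, must be reached, otherwise tracks have no
#'   normalization reference).
#' @param n_tracks number of tracks (>= 1).
#' @param scenario a [synthetic_scenario()].
#' @param s_seed_range range of initial meridional positions (um);
#'   default: pole to 80% of the meridian.
#' @return A list of [qdot_track()]s; attribute `dh_um` carries the shared
#'   growth series.
#' @export
synth_qdot_tracks <- function(velocity, meridian, n_tracks, scenario,
                              s_seed_range = NULL) {
  stopifnot(n_tracks >= 1)
  if (max(meridian$phi) < pi / 2 - 1e-3)
    stop("meridian has no cylinder flank: tracks need an equator")
  dh <- .growth_series(scenario)
  f <- phi_of_s(meridian)
  if (is.null(s_seed_range)) s_seed_range <- c(0, 0.8 * max(meridian$s))
  set.seed(scenario$seed + 29L)
  s0 <- stats::runif(n_tracks, s_seed_range[1], s_seed_range[2])
  if (n_tracks >= 1) s0[1] <- s_seed_range[1]  # always sample near the start
  tracks <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    s <- numeric(length(dh) + 1)
    s[1] <- s0[i]
    for (t in seq_along(dh)) {
      step <- vp_eval(velocity, f(s[t])) * dh[t]
      if (scenario$noise_sd$track > 0)
        step <- step + stats::rnorm(1, 0, scenario$noise_sd$track)
      s[t + 1] <- s[t] + step   # phi(s) extends as pi/2 beyond the grid
    }
    tracks[[i]] <- qdot_track(s, dh, id = sprintf("qdot%02d", i))
  }
  attr(tracks, "dh_um") <- dh
  tracks
}

#' Synthetic cortical fluorescence profiles
#'
#' Generates per-frame raw intensity profiles for one or more synthetic
#' "markers": a ground-truth bell-shaped profile of the chosen family plus
#' independent Gaussian noise per frame, with a constant background
#' offset.
#'
#' @param family `"gaussian"` (param `sigma`), `"cosine_power"` (params
#'   `W` half-width and `p` exponent) or `"plateau"` (param `W` full
#'   width).
#' @param params named list of family parameters (all > 0).
#' @param n_cells number of cells (independent noise).
#' @param n_frames frames per cell.
#' @param scenario a [synthetic_scenario()].
#' @param s_max half-span of the pole-centred grid (um).
#' @param n_s grid points.
#' @param amplitude peak intensity above background.
#' @param background constant offset.
#' @return A list per cell, each with `s_um`, `frames` (n_frames x n_s
#'   matrix) and `truth` (normalized ground-truth profile).
#' @export
synth_fluorescence_profiles <- function(family = c("gaussian", "cosine_power",
                                                   "plateau"),
                                        params = list(sigma = 1),
                                        n_cells = 1, n_frames = 1,
                                        scenario = synthetic_scenario(),
                                        s_max = 6, n_s = 241,
                                        amplitude = 100, background = 20) {
  family <- match.arg(family)
  stopifnot(n_frames >= 1, all(unlist(params) > 0))
  s <- seq(-s_max, s_max, length.out = n_s)
  truth <- switch(family,
    gaussian = exp(-s^2 / (2 * params$sigma^2)),
    cosine_power = ifelse(abs(s) < params$W,
                          cos(pi * s / (2 * params$W))^params$p, 0),
    plateau = as.numeric(abs(s) <= params$W / 2))
  set.seed(scenario$seed + 41L)
  lapply(seq_len(n_cells), function(i) {
    fr <- matrix(background + amplitude * rep(truth, each = n_frames),
                 n_frames, n_s)
    if (scenario$noise_sd$profile > 0)
      fr <- fr + matrix(stats::rnorm(n_frames * n_s, 0,
                                     scenario$noise_sd$profile),
                        n_frames, n_s)
    list(s_um = s, frames = fr, truth = truth)
  })
}

#' Synthetic plasmolysed/turgid contour pair
#'
#' Runs the forward elastic model: the plasmolysed (stress-free) shape is
#' a resting half-cell meridian; the turgid shape is its equilibrium
#' inflation at the ground-truth elastic parameters. Both are returned as
#' closed planar outlines (um) with optional Gaussian contour noise, plus
#' the exact half meridians for noise-free work.
#'
#' @param params ground-truth [elastic_params()].
#' @param resting resting half-cell [meridian_contour()] (pole to
#'   mid-plane); default: hemisphere cap + flank of radius 2 um.
#' @param noise_sd contour noise sd (um) applied to outline points.
#' @param seed seed for the noise.
#' @param model shell model for the forward inflation.
#' @return A list with `plasmolysed`, `turgid` (closed outlines, data
#'   frames x/y in um), `plasmolysed_meridian`, `turgid_meridian`, and
#'   `params` (ground truth).
#' @export
synth_plasmolysis_pair <- function(params,
                                   resting = cap_cylinder_meridian(2, flank = 4,
                                                                   n = 81),
                                   noise_sd = 0, seed = 1L,
                                   model = "membrane") {
  sol <- inflate_shell(resting, params, pressure = 1, model = model)
  mirror_outline <- function(r, z) {
    # half meridian (pole at z=0, mid-plane at z=zmin) -> closed cell
    # outline: reflect across the mid-plane and the axis
    xr <- -z                      # pole at x = 0, mid-plane at x = -zmin
    L <- max(xr)
    x_full <- c(xr, 2 * L - rev(xr)[-1])
    y_full <- c(r, rev(r)[-1])
    x <- c(x_full, rev(x_full)[-1])
    y <- c(y_full, -rev(y_full)[-1])
    keep <- c(TRUE, sqrt(diff(x)^2 + diff(y)^2) > 1e-9)
    data.frame(x = x[keep], y = y[keep])
  }
  o_p <- mirror_outline(resting$r, resting$z)
  o_t <- mirror_outline(sol$r, sol$z)
  if (noise_sd > 0) {
    set.seed(seed + 59L)
    o_p$x <- o_p$x + stats::rnorm(nrow(o_p), 0, noise_sd)
    o_p$y <- o_p$y + stats::rnorm(nrow(o_p), 0, noise_sd)
    o_t$x <- o_t$x + stats::rnorm(nrow(o_t), 0, noise_sd)
    o_t$y <- o_t$y + stats::rnorm(nrow(o_t), 0, noise_sd)
  }
  list(plasmolysed = o_p, turgid = o_t,
       plasmolysed_meridian = resting,
       turgid_meridian = sol$deformed,
       params = params)
}
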