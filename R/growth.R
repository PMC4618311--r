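# Morphogenetic growth model: the stress-free (resting) wall grows by
# incorporation of new material while the turgid shape is its elastic
# equilibrium under pressure. Growth of the resting metric is isotropic
# and multiplicative, proportional to the local incorporation rate; the
# circumferential bias of the *observed* expansion then emerges
# mechanically from the force balance, not from the growth rule.
#
# The resting state is a material metric, not necessarily a planar curve:
# per element, a resting meridional length ds0 and a resting
# circumferential radius rb0. Incorporation is indexed by deformed
# (turgid) arclength from the pole, because fluorescence and fiducial
# data live on the turgid surface.

# membrane shell spec from a resting metric (possibly incompatible)
.shell_spec_metric <- function(ds0, rb0, params, pressure, z_base,
                               stiffness_radius) {
  N <- length(ds0) + 1L
  t_abs <- params$thickness_to_radius * stiffness_radius
  C <- params$E_over_P * t_abs
  r0n <- c(0, (rb0[-1] + rb0[-length(rb0)]) / 2, rb0[length(rb0)])
  ell0 <- (ds0[-length(ds0)] + ds0[-1]) / 2
  list(N = N, ds0 = ds0, rb0 = pmax(rb0, 1e-9), r0n = r0n, ell0 = ell0,
       ks0 = numeric(N), kt0 = numeric(N - 1), C = C, D = 0,
       nu = params$nu, P = pressure, bc = "symmetry",
       free_r = 2:N, free_z = 1:(N - 1),
       r_fix = r0n, z_fix = c(numeric(N - 1), z_base))
}

#' Canonical bell-shaped wall-incorporation profile
#'
#' A Gaussian deposition profile `exp(-(s/sigma)^2)` of the meridional
#' distance from the pole. The default width `sigma = 2` um is calibrated
#' so that, at the reference wall properties (E/P = 40, nu = 0.3), the
#' growth model's steady cell has the observed radius (~2 um) and about
#' 90% of its wall expansion falls within 3 um of the pole, the measured
#' localization of tip growth.
#'
#' @param sigma Gaussian width (um).
#' @return A function of meridional distance `s` (um).
#' @export
canonical_incorporation <- function(sigma = 2) {
  force(sigma)
  function(s) exp(-(s / sigma)^2)
}

#' Simulate growth-domain evolution (wall incorporation + elasticity)
#'
#' Iterates the morphogenetic model: (1) inflate the resting meridian to
#' elastic equilibrium under turgor, (2) evaluate the incorporation
#' profile at the deformed arclength of each material element, (3) grow
#' the resting metric multiplicatively and isotropically in proportion to
#' local incorporation, and repeat. The time step is chosen so the
#' largest per-step areal growth increment stays below `step_strain`.
#'
#' @param initial_cap a [meridian_contour()] half-cell (pole, cap and a
#'   flank reaching the mid-plane) taken as the initial resting shape.
#' @param incorporation function of deformed arclength from the pole (um)
#'   returning a non-negative areal deposition rate; must be localized
#'   (decay along the meridian). Only its shape matters: amplitude
#'   rescales time.
#' @param params an [elastic_params()].
#' @param steps number of growth steps.
#' @param step_strain maximum areal growth increment per step.
#' @param s_grid fixed pole-frame grid (um) for the curvature kymograph.
#' @param record_every record a kymograph column every this many steps.
#' @return An object of class `growth_simulation`: list with `kymograph`
#'   (a [curvature_kymograph()]), `final` (deformed meridian),
#'   `convergence` (max |d kappa| per step on the grid), `tip_advance`
#'   (um per step), `area_balance` (relative error of resting-area
#'   bookkeeping per step), `s_material` (deformed arclength of material
#'   nodes at the last two steps), `dh_last`, `params`, `incorporation`.
#' @export
simulate_end_evolution <- function(initial_cap, incorporation, params,
                                   steps = 150, step_strain = 0.01,
                                   s_grid = seq(0, 5, length.out = 101),
                                   record_every = 5L, solver_tol = 2e-6) {
  stopifnot(inherits(initial_cap, "meridian_contour"),
            inherits(params, "elastic_params"))
  Itest <- incorporation(seq(0, max(initial_cap$s), length.out = 50))
  if (any(Itest < 0)) stop("incorporation must be non-negative")
  if (max(Itest) > 0 && Itest[50] > 0.05 * max(Itest))
    stop("incorporation does not decay along the meridian: no steady tip")
  r <- initial_cap$r; z <- initial_cap$z
  N <- length(r)
  ds0 <- sqrt(diff(r)^2 + diff(z)^2)
  r0n <- r                      # nodal resting radius (material state)
  Rref <- max(r)
  L_target <- sum(ds0)          # resting domain length kept by truncation
  kappa_rec <- list(); rec_steps <- integer(0)
  conv <- rep(NA_real_, steps); tip <- rep(NA_real_, steps)
  abal <- rep(NA_real_, steps)
  kappa_prev <- NULL
  s_def_prev <- NULL
  s_mat_last <- NULL; dh_last <- NA_real_
  final_m <- NULL
  warm <- list(r = r, z = z)
  for (st in seq_len(steps)) {
    rb0 <- (r0n[-1] + r0n[-N]) / 2
    sp <- .shell_spec_metric(ds0, rb0, params, pressure = 1,
                             z_base = warm$z[N], stiffness_radius = Rref)
    sol <- .shell_solve(sp, warm$r, warm$z, tol = solver_tol)
    if (sol$residual > 10 * solver_tol)
      stop(sprintf("equilibrium failed to converge at step %d (residual %.3g); use a smaller step", st, sol$residual))
    warm <- list(r = sol$r, z = sol$z)
    dsd <- sqrt(diff(sol$r)^2 + diff(sol$z)^2)
    s_def <- c(0, cumsum(dsd))
    m <- meridian_from_rz(sol$r, sol$z)
    final_m <- m
    # pole-frame curvature on the fixed grid
    kap <- stats::approx(m$s, m$kappa_s, xout = s_grid, rule = 2)$y
    if (!is.null(kappa_prev)) conv[st] <- max(abs(kap - kappa_prev))
    kappa_prev <- kap
    if (st %% record_every == 1 || record_every == 1) {
      kappa_rec[[length(kappa_rec) + 1]] <-
        data.frame(s_um = s_grid, kappa_s = kap)
      rec_steps <- c(rec_steps, st)
    }
    if (!is.null(s_def_prev)) {
      tip[st] <- s_def[N] - s_def_prev[N]
      s_mat_last <- list(prev = s_def_prev, cur = s_def)
      dh_last <- tip[st]
    }
    s_def_prev <- s_def
    # grow the resting metric (isotropic, multiplicative)
    s_mid <- (s_def[-1] + s_def[-N]) / 2
    I_e <- incorporation(s_mid)
    I_n <- incorporation(s_def)
    Imax <- max(I_e)
    if (Imax > 0) {
      dt <- step_strain / Imax
      A_before <- sum(2 * pi * rb0 * ds0)
      inc <- sum(2 * pi * rb0 * ds0 * I_e * dt)
      ds0 <- ds0 * exp(I_e * dt / 2)
      r0n <- r0n * exp(I_n * dt / 2)
      A_after <- sum(2 * pi * (r0n[-1] + r0n[-N]) / 2 * ds0)
      abal[st] <- abs((A_after - A_before) - inc) / max(inc, 1e-300)
      # remesh resting metric to near-uniform spacing (cubic splines keep
      # the pole-region metric smooth); the inert far flank is truncated
      # so the tip stays resolved as the domain elongates (the cut sits
      # mid-cylinder, where the symmetry boundary condition is exact)
      s0 <- c(0, cumsum(ds0))
      if (max(ds0) / min(ds0) > 1.8 || s0[N] > 1.15 * L_target) {
        s0n <- seq(0, min(s0[N], L_target), length.out = N)
        r0n <- stats::spline(s0, r0n, xout = s0n, method = "natural")$y
        rn <- stats::spline(s0, sol$r, xout = s0n, method = "natural")$y
        zn <- stats::spline(s0, sol$z, xout = s0n, method = "natural")$y
        rn[1] <- 0; r0n[1] <- 0
        r0n <- pmax(r0n, 0)
        ds0 <- diff(s0n)
        warm <- list(r = rn, z = zn)
        s_def_prev <- NULL   # material correspondence broken by remesh
      }
    }
  }
  kymo <- curvature_kymograph(kappa_rec, times = rec_steps, s_grid = s_grid)
  structure(list(kymograph = kymo, final = final_m, convergence = conv,
                 tip_advance = tip, area_balance = abal,
                 s_material = s_mat_last, dh_last = dh_last,
                 params = params, incorporation = incorporation,
                 converged = !is.na(conv[steps]) &&
                   conv[steps] < 1e-3),
            class = "growth_simulation")
}

#' @export
print.growth_simulation <- function(x, ...) {
  n <- length(x$convergence)
  cat(sprintf(
    "growth_simulation: %d steps, final |dkappa| %.2g 1/um/step, tip advance %.3g um/step\n",
    n, x$convergence[n], x$dh_last))
  invisible(x)
}

#' Measure the expansion profile predicted by a growth simulation
#'
#' Advects virtual fiducials (the material nodes) between the last two
#' equilibria of a converged simulation and analyses them exactly as
#' experimental fiducial tracks: relative displacement `v = ds/dh`
#' (with `dh` the tip advance), constrained velocity fit, then strain
#' rates on the final meridian.
#'
#' @param sim a [simulate_end_evolution()] result.
#' @param strict error when the simulation has not met the convergence
#'   threshold (default TRUE; the property scan relaxes this for short
#'   screening runs).
#' @return A list with `profile` (the [strain_rates()] expansion profile
#'   obtained through the constrained velocity fit, i.e. the same pipeline
#'   applied to experimental fiducials), `profile_direct` (nonparametric
#'   strain rates from raw node displacements), `velocity` (fitted
#'   [velocity_profile()]) and `samples` (raw displacement samples).
#' @export
predicted_expansion <- function(sim, strict = TRUE) {
  stopifnot(inherits(sim, "growth_simulation"))
  if (strict && !isTRUE(sim$converged))
    stop("simulation has not converged; run more steps")
  if (is.null(sim$s_material))
    stop("no material displacement recorded")
  s0 <- sim$s_material$prev; s1 <- sim$s_material$cur
  dh <- sim$dh_last
  v <- (s1 - s0) / dh
  f <- phi_of_s(sim$final)
  keep <- s0 <= max(sim$final$s)
  samples <- data.frame(s_um = s0[keep], phi = f(s0[keep]), v = v[keep])
  vfit <- fit_velocity_profile(samples)
  prof <- strain_rates(vfit, sim$final)
  # nonparametric route: differentiate the raw displacement field
  m <- sim$final
  rr <- stats::approx(m$s, m$r, xout = samples$s_um, rule = 2)$y
  eps_s <- as.numeric(pracma::gradient(samples$v, samples$s_um))
  eps_t <- c(eps_s[1], (samples$v * cos(samples$phi) / rr)[-1])
  direct <- data.frame(s_um = samples$s_um, v = samples$v,
                       eps_s = eps_s, eps_theta = eps_t,
                       areal = eps_s + eps_t)
  list(profile = prof, profile_direct = direct, velocity = vfit,
       samples = samples)
}

#' Scan material properties against a target expansion profile
#'
#' Runs the growth model across a grid of (E/P, nu), measures each
#' predicted areal-expansion profile, and scores the misfit to a target
#' profile (surface-weighted L2 on normalized profiles). If the target
#' carries a confidence band (`areal_sd` column), the admissible region
#' within the band is reported, along with the admissible point closest
#' to a reference estimate.
#'
#' @param target data frame with `s_um`, `areal` (and optionally
#'   `areal_sd`); e.g. an [strain_rates()] profile of measured data.
#' @param EP_grid,nu_grid grid values.
#' @param initial_cap,incorporation,steps,step_strain passed to
#'   [simulate_end_evolution()]; by default incorporation follows the
#'   target areal profile itself.
#' @param reference c(E/P, nu) used to select among admissible points.
#' @param band_z z-multiplier for the confidence band (1.96 ~ 95%).
#' @return A list with `scores` (data frame E_over_P, nu, score,
#'   admissible, ok), `best` (argmin row), `selected` (admissible point
#'   nearest the reference, or NULL).
#' @export
material_property_scan <- function(target, EP_grid, nu_grid,
                                   initial_cap = cap_cylinder_meridian(2, flank = 4, n = 51),
                                   incorporation = NULL,
                                   steps = 300, step_strain = 0.015,
                                   reference = c(40, 0.3), band_z = 1.96) {
  if (is.null(incorporation)) {
    gfun <- stats::approxfun(target$s_um, pmax(target$areal, 0),
                             yright = 0, rule = 2)
    incorporation <- gfun
  }
  norm_on <- function(s, a, r) {
    w <- 2 * pi * r
    tot <- pracma::trapz(s, pmax(a, 0) * w)
    a / tot
  }
  grid <- expand.grid(E_over_P = EP_grid, nu = nu_grid)
  grid$score <- NA_real_; grid$ok <- FALSE; grid$admissible <- FALSE
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      p <- elastic_params(grid$E_over_P[i], grid$nu[i])
      sim <- simulate_end_evolution(initial_cap, incorporation, p,
                                    steps = steps, step_strain = step_strain)
      pe <- predicted_expansion(sim, strict = FALSE)
      sq <- target$s_um
      rA <- stats::approx(pe$profile$s_um, pe$profile$areal, xout = sq,
                          rule = 2)$y
      r_t <- stats::approx(sim$final$s, sim$final$r, xout = sq, rule = 2)$y
      an <- norm_on(sq, rA, r_t)
      tn <- norm_on(sq, target$areal, r_t)
      w <- 2 * pi * r_t
      sc <- sqrt(pracma::trapz(sq, (an - tn)^2 * w) /
                   pracma::trapz(sq, tn^2 * w))
      adm <- if ("areal_sd" %in% names(target)) {
        sdn <- target$areal_sd / pracma::trapz(sq, pmax(target$areal, 0) * w)
        all(abs(an - tn) <= band_z * sdn + 1e-12)
      } else NA
      list(score = sc, admissible = adm)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      grid$score[i] <- res$score
      grid$ok[i] <- TRUE
      grid$admissible[i] <- isTRUE(res$admissible)
    }
  }
  if (!any(grid$ok)) stop("all grid points failed")
  best <- grid[which.min(grid$score), ]
  selected <- NULL
  if (any(grid$admissible, na.rm = TRUE)) {
    adm <- grid[which(grid$admissible), ]
    d <- sqrt(((adm$E_over_P - reference[1]) / reference[1])^2 +
                (adm$nu - reference[2])^2)
    selected <- adm[which.min(d), ]
  } else if ("areal_sd" %in% names(target)) {
    warning("no grid point falls within the target confidence band")
  }
  list(scores = grid, best = best, selected = selected)
}

#' Steady end shape driven by a marker distribution
#'
#' Uses a cortical marker's conditioned fluorescence profile as a proxy
#' for the wall-incorporation profile and runs the growth model to its
#' steady shape. Amplitude scaling of the profile only rescales time, so
#' only the profile shape matters.
#'
#' @param profile a conditioned fluorescence profile (see
#'   [condition_profile()]) or any data frame with `s_um`, `gamma`.
#' @param params an [elastic_params()].
#' @param initial_cap,steps,step_strain see [simulate_end_evolution()].
#' @return A list with `meridian` (steady deformed shape), `end_width`
#'   (um, diameter of the tube emerging below the growth zone),
#'   `pole_curvature` (1/um), `fwha_input` (um) and `sim`.
#' @export
marker_driven_shape <- function(profile, params,
                                initial_cap = cap_cylinder_meridian(2, flank = 4, n = 51),
                                steps = 220, step_strain = 0.015) {
  df <- as.data.frame(profile)
  if (!"gamma" %in% names(df)) stop("profile needs a 'gamma' column")
  half <- df[df$s_um >= 0, ]
  g <- stats::approxfun(half$s_um, pmax(half$gamma, 0), yright = 0, rule = 2)
  sim <- simulate_end_evolution(initial_cap, g, params, steps = steps,
                                step_strain = step_strain)
  m <- sim$final
  gm <- g(m$s)
  s_cut <- m$s[min(which(gm < 0.02 * max(gm)))]
  i_w <- which.min(abs(m$s - (s_cut + 0.5)))
  list(meridian = m,
       end_width = 2 * m$r[i_w],
       pole_curvature = m$kappa_s[1],
       fwha_input = central_width(df, 0.5),
       sim = sim)
}
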