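# Axisymmetric elastic shell solver.
#
# The wall is a thin axisymmetric shell discretized along its meridian.
# Equilibrium under uniform internal (turgor) pressure is found by
# minimizing the total potential energy
#     U = membrane strain energy (+ bending energy) - P * enclosed volume,
# over the nodal coordinates (r_i, z_i), i.e. pressure acts as a follower
# load always normal to the deformed surface. The constitutive law is an
# isotropic linear relation between 2-D stress resultants and engineering
# strains, applied at finite strain through the deformed metric:
#     W = C / (2 (1 - nu^2)) * (es^2 + 2 nu es et + et^2) per resting area,
# with es = ds/ds0 - 1 (meridional) and et = r/r0 - 1 (circumferential),
# C = (E/P) * t the membrane stiffness in pressure units. The optional
# bending term penalizes changes of the meridional and circumferential
# curvatures relative to the resting configuration with plate-like
# stiffness D = C t^2 / (12 (1 - nu^2)) (thin-shell Kirchhoff-Love limit;
# used for high-curvature resting shapes such as the septum).
#
# Boundary conditions: pole (r = 0, z free); far end either a symmetry
# plane (z fixed, r free; exact for the mid-plane of a closed cell or a
# truncated cylinder) or clamped (r and z fixed; septum junction).

# build solver spec from resting nodal geometry
.shell_spec <- function(r0, z0, params, pressure, model, bc,
                        stiffness_radius = NULL) {
  N <- length(r0)
  stopifnot(length(z0) == N, N >= 8)
  dr0 <- diff(r0); dz0 <- diff(z0)
  ds0 <- sqrt(dr0^2 + dz0^2)
  if (any(ds0 <= 0)) stop("degenerate resting element")
  rb0 <- (r0[-1] + r0[-N]) / 2
  if (is.null(stiffness_radius)) stiffness_radius <- max(r0)
  t_abs <- params$thickness_to_radius * stiffness_radius
  C <- params$E_over_P * t_abs
  D <- if (model == "bending_shear") C * t_abs^2 / (12 * (1 - params$nu^2)) else 0
  th0 <- atan2(dz0, dr0)
  dth0 <- diff(th0); dth0 <- atan2(sin(dth0), cos(dth0))
  ell0 <- (ds0[-length(ds0)] + ds0[-1]) / 2
  ks0 <- c(0, -dth0 / ell0, 0)              # nodal resting curvature
  kt0 <- (-dz0 / ds0) / pmax(rb0, 1e-12)    # element resting circ. curvature
  list(N = N, ds0 = ds0, rb0 = pmax(rb0, 1e-9), r0n = r0, ell0 = ell0,
       ks0 = ks0, kt0 = kt0, C = C, D = D, nu = params$nu, P = pressure,
       bc = bc,
       free_r = if (bc == "symmetry") 2:N else 2:(N - 1),
       free_z = 1:(N - 1),
       r_fix = r0, z_fix = z0)
}

# total potential energy and (optionally) its gradient wrt all nodal coords
.shell_energy <- function(r, z, sp, grad = FALSE) {
  N <- sp$N
  dr <- diff(r); dz <- diff(z)
  ds <- sqrt(dr^2 + dz^2)
  lam_s <- ds / sp$ds0
  rb <- (r[-1] + r[-N]) / 2
  es <- lam_s - 1
  et <- rb / sp$rb0 - 1
  dA0 <- 2 * pi * sp$rb0 * sp$ds0
  k2 <- sp$C / (2 * (1 - sp$nu^2))
  Em <- sum(k2 * (es^2 + 2 * sp$nu * es * et + et^2) * dA0)
  V <- -pi * sum(rb^2 * dz)
  E <- Em - sp$P * V
  Eb <- 0
  if (sp$D > 0) {
    th <- atan2(dz, dr)
    dth <- diff(th); dth <- atan2(sin(dth), cos(dth))
    ks <- c(0, -dth / sp$ell0, 0)
    kt <- (-dz / ds) / pmax(rb, 1e-9)
    dks <- ks - sp$ks0
    dkt <- kt - sp$kt0
    dA0n <- 2 * pi * sp$r0n * c(0, sp$ell0, 0)
    Db <- sp$D / 2
    Eb <- sum(Db * dkt^2 * dA0) + sum(Db * dks[2:(N - 1)]^2 * dA0n[2:(N - 1)])
    E <- E + Eb
  }
  if (!grad) return(E)
  g_r <- numeric(N); g_z <- numeric(N)
  # membrane
  dWdes <- k2 * (2 * es + 2 * sp$nu * et) * dA0
  dWdet <- k2 * (2 * et + 2 * sp$nu * es) * dA0
  gdr <- dWdes * dr / (ds * sp$ds0)
  gdz <- dWdes * dz / (ds * sp$ds0)
  grb <- dWdet / sp$rb0
  # pressure: E -= P*V, V = -pi sum rb^2 dz
  gdz <- gdz + sp$P * pi * rb^2
  grb <- grb + sp$P * 2 * pi * rb * dz
  if (sp$D > 0) {
    th <- atan2(dz, dr)
    dth <- diff(th); dth <- atan2(sin(dth), cos(dth))
    ks <- c(0, -dth / sp$ell0, 0)
    kt <- (-dz / ds) / pmax(rb, 1e-9)
    dks <- ks - sp$ks0
    dkt <- kt - sp$kt0
    dA0n <- 2 * pi * sp$r0n * c(0, sp$ell0, 0)
    Db <- sp$D / 2
    # circumferential bending (element-based)
    ce <- 2 * Db * dkt * dA0
    gdr <- gdr + ce * (dz * dr / (ds^3 * rb))
    gdz <- gdz + ce * (-(dr^2) / (ds^3 * rb))
    grb <- grb + ce * (-kt / rb)             # d kt / d rb = -kt / rb
    # meridional bending (node-based): kappa_s_i = -(th_i - th_{i-1}) / ell0
    cn <- numeric(N)
    cn[2:(N - 1)] <- 2 * Db * dks[2:(N - 1)] * dA0n[2:(N - 1)] *
      (-1 / sp$ell0)
    A_e <- numeric(N - 1)
    e_idx <- seq_len(N - 1)
    plus <- e_idx >= 2 & e_idx <= N - 1
    A_e[plus] <- A_e[plus] + cn[e_idx[plus]]
    minus <- (e_idx + 1) <= N - 1
    A_e[minus] <- A_e[minus] - cn[e_idx[minus] + 1]
    gdr <- gdr + A_e * (-dz / ds^2)
    gdz <- gdz + A_e * (dr / ds^2)
  }
  # scatter element-diff gradients to nodes
  M <- N - 1
  g_r[1:M] <- g_r[1:M] - gdr
  g_r[2:N] <- g_r[2:N] + gdr
  g_z[1:M] <- g_z[1:M] - gdz
  g_z[2:N] <- g_z[2:N] + gdz
  g_r[1:M] <- g_r[1:M] + grb / 2
  g_r[2:N] <- g_r[2:N] + grb / 2
  list(E = E, g_r = g_r, g_z = g_z)
}

# minimize potential energy; returns nodal (r, z) and diagnostics
.shell_solve <- function(sp, r_init, z_init, maxit = 4000, tol = 1e-4) {
  fr <- sp$free_r; fz <- sp$free_z
  pack <- function(r, z) c(r[fr], z[fz])
  unpack <- function(p) {
    r <- sp$r_fix; z <- sp$z_fix
    r[fr] <- p[seq_along(fr)]
    z[fz] <- p[length(fr) + seq_along(fz)]
    r[1] <- 0
    list(r = r, z = z)
  }
  fn <- function(p) {
    u <- unpack(p)
    .shell_energy(u$r, u$z, sp)
  }
  gr <- function(p) {
    u <- unpack(p)
    g <- .shell_energy(u$r, u$z, sp, grad = TRUE)
    c(g$g_r[fr], g$g_z[fz])
  }
  scale <- sp$P * max(sp$r0n)^2 + sp$C * 1e-3
  p0 <- pack(r_init, z_init)
  hist <- numeric(0)
  best <- NULL
  for (try in 1:3) {
    opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10,
                                       pgtol = tol * scale / 10))
    u <- unpack(opt$par)
    g <- .shell_energy(u$r, u$z, sp, grad = TRUE)
    res <- max(abs(c(g$g_r[fr], g$g_z[fz]))) / scale
    hist <- c(hist, res)
    if (is.null(best) || res < best$residual)
      best <- list(r = u$r, z = u$z, residual = res, energy = opt$value)
    if (res < tol) break
    p0 <- pack(u$r, u$z)
  }
  if (best$residual > 100 * tol)
    stop(sprintf("shell solver did not converge; residual history: %s",
                 paste(signif(hist, 3), collapse = ", ")))
  best$residual_history <- hist
  best$converged <- best$residual < tol
  best
}
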