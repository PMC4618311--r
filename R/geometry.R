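#' Planar cell outline
#'
#' An ordered, closed polyline of anchor points delineating a cell contour
#' in an image. Coordinates are in pixels (0-based image convention, x to
#' the right, y down); `pixel_size` converts to um.
#'
#' @param x,y numeric coordinates (pixels). The polygon is implicitly
#'   closed (do not repeat the first point).
#' @param pixel_size um per pixel.
#' @param frame frame index.
#' @param time_min timestamp in minutes.
#' @return An object of class `planar_outline`.
#' @export
planar_outline <- function(x, y, pixel_size = 0.067, frame = 1L,
                           time_min = 0) {
  stopifnot(length(x) == length(y), length(x) >= 3, pixel_size > 0)
  if (.polygon_self_intersects(x, y))
    stop("outline is self-intersecting")
  structure(data.frame(x = x, y = y),
            pixel_size = pixel_size, frame = frame, time_min = time_min,
            class = c("planar_outline", "data.frame"))
}

# crude O(n^2) segment-pair check; outlines have <= a few hundred anchors
.polygon_self_intersects <- function(x, y) {
  n <- length(x)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  seg_int <- function(i, j) {
    p1 <- c(xs[i], ys[i]); p2 <- c(xs[i + 1], ys[i + 1])
    p3 <- c(xs[j], ys[j]); p4 <- c(xs[j + 1], ys[j + 1])
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n > 400) return(FALSE)  # skip the quadratic check for dense outlines
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- setdiff(seq(i + 2, jmax), i)
    for (j in js) if (seg_int(i, j)) return(TRUE)
  }
  FALSE
}

#' Resample a closed outline at uniform arclength spacing
#'
#' Periodic cubic-spline interpolation through the anchor points, then
#' uniform resampling along the interpolated curve.
#'
#' @param outline a [planar_outline()].
#' @param spacing target spacing in pixels (default 0.1 px, fine enough
#'   that turning-angle curvature converges for cell-scale features).
#' @param n alternatively, an explicit number of points.
#' @return A [planar_outline()] with the new points.
#' @export
resample_outline <- function(outline, spacing = 0.1, n = NULL) {
  x <- outline$x; y <- outline$y
  xs <- c(x, x[1]); ys <- c(y, y[1])
  tt <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  L <- tt[length(tt)]
  if (is.null(n)) n <- max(16L, round(L / spacing))
  tq <- seq(0, L, length.out = n + 1)[-(n + 1)]
  fx <- stats::splinefun(tt, xs, method = "periodic")
  fy <- stats::splinefun(tt, ys, method = "periodic")
  planar_outline(fx(tq), fy(tq),
                 pixel_size = attr(outline, "pixel_size"),
                 frame = attr(outline, "frame"),
                 time_min = attr(outline, "time_min"))
}

#' Meridional curvature along a cell outline
#'
#' Turning-angle curvature `kappa_s(s) = alpha(s) / l`: the outline is
#' resampled at fine uniform spacing `l`, and the curvature at each point is
#' the rotation angle between successive contour segments divided by the
#' segment length. Positive for outward-convex contours traversed in
#' either direction.
#'
#' @param outline a [planar_outline()].
#' @param segment_length segment length `l` in um (default: 0.1 pixel).
#' @return A data frame with columns `s_um` (arclength along the outline,
#'   from the first resampled point) and `kappa_s` (1/um).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 61)[-61]
#' oc <- planar_outline(30 + 20 * cos(th), 30 + 20 * sin(th), pixel_size = 0.1)
#' k <- meridional_curvature(oc)   # circle radius 2 um -> kappa 0.5
#' @export
meridional_curvature <- function(outline,
                                 segment_length = 0.1 * attr(outline, "pixel_size")) {
  px <- attr(outline, "pixel_size")
  if (segment_length > 0.5 * px)
    warning("segment length is coarse relative to the pixel grid")
  res <- resample_outline(outline, spacing = segment_length / px)
  x <- res$x * px; y <- res$y * px
  n <- nrow(res)
  # closed curve: wrap neighbours
  xn <- c(x, x[1]); yn <- c(y, y[1])
  dx <- diff(xn); dy <- diff(yn)
  th <- atan2(dy, dx)
  dth <- diff(c(th, th[1]))
  dth <- atan2(sin(dth), cos(dth))
  l <- sqrt(dx^2 + dy^2)
  kappa <- dth / ((l + c(l[-1], l[1])) / 2)
  # sign convention: make the dominant (convex) sign positive
  if (sum(dth) < 0) kappa <- -kappa
  s <- c(0, cumsum(l))[seq_len(n)]
  data.frame(s_um = s, kappa_s = kappa)
}

#' Locate the growth pole between two outlines
#'
#' The pole is the Eulerian reference point of a growth domain: the contour
#' point of the first outline whose orthogonal path (along the local
#' outward normal) to the last outline is longest. An optional manual
#' `shift` (in resampled points) displaces the returned pole along the
#' contour, mirroring the manual symmetry correction used when spurious
#' asymmetry misplaces the automatic pole.
#'
#' @param first_outline,last_outline [planar_outline()]s of the same cell.
#' @param spacing resampling spacing (px) for the search.
#' @param shift integer manual shift (resampled points, signed).
#' @return A list with `point` (x, y on the first outline), `index`
#'   (resampled index), `path_length` (px) and the resampled outline used.
#' @export
locate_pole <- function(first_outline, last_outline, spacing = 0.5,
                        shift = 0L) {
  a <- resample_outline(first_outline, spacing = spacing)
  b <- resample_outline(last_outline, spacing = spacing)
  d <- .orthogonal_path_lengths(a$x, a$y, b$x, b$y)
  if (all(!is.finite(d)) || max(d, na.rm = TRUE) < 0.5)  # < half a pixel
    stop("no growth; pole undefined (outlines identical)")
  i <- which.max(d)
  i <- ((i - 1 + shift) %% nrow(a)) + 1
  list(point = c(x = a$x[i], y = a$y[i]), index = i,
       path_length = d[i], outline = a)
}

# length of the outward-normal ray from each point of polygon A to its
# first intersection with polygon B; NA when the ray misses B.
.orthogonal_path_lengths <- function(ax, ay, bx, by) {
  n <- length(ax)
  tx <- (c(ax[-1], ax[1]) - c(ax[n], ax[-n])) / 2
  ty <- (c(ay[-1], ay[1]) - c(ay[n], ay[-n])) / 2
  tl <- sqrt(tx^2 + ty^2)
  nxv <- ty / tl; nyv <- -tx / tl
  # orient each normal away from the polygon centroid (robust for the
  # convex-ish rod outlines this is used on)
  cx0 <- mean(ax); cy0 <- mean(ay)
  flip <- (nxv * (ax - cx0) + nyv * (ay - cy0)) < 0
  nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]
  m <- length(bx)
  bx2 <- c(bx, bx[1]); by2 <- c(by, by[1])
  ex <- diff(bx2); ey <- diff(by2)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    # ray p + t n vs segments q + u e, t >= 0, 0 <= u <= 1
    den <- nxv[i] * ey - nyv[i] * ex
    ok <- abs(den) > 1e-12
    qx <- bx2[-(m + 1)] - ax[i]; qy <- by2[-(m + 1)] - ay[i]
    t <- (qx * ey - qy * ex) / den
    u <- (qx * nyv[i] - qy * nxv[i]) / (-den)
    hit <- ok & t > 1e-3 & u >= 0 & u <= 1
    if (any(hit)) out[i] <- min(t[hit])
  }
  out
}

#' Canonical (symmetrized, averaged) end-shape curvature
#'
#' Averages many meridional curvature profiles at fixed meridional distance
#' from the pole and symmetrizes by averaging the left and right sides, the
#' standard way a canonical growth-domain geometry is obtained from
#' time-lapse data.
#'
#' @param profiles a list of data frames with columns `s_um` (signed
#'   meridional distance from the pole) and `kappa_s`.
#' @param s_grid common non-negative grid to resample on; default: union
#'   range at median resolution.
#' @return A data frame `s_um` (>= 0), `kappa_mean`, `kappa_sd`, `n`.
#' @export
canonical_end_shape <- function(profiles, s_grid = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(s_grid)) {
    smax <- min(vapply(profiles, function(p) max(abs(p$s_um)), 0))
    s_grid <- seq(0, smax, length.out = 101)
  }
  halves <- list()
  for (p in profiles) {
    for (sgn in c(1, -1)) {
      side <- p[sign(p$s_um) %in% c(0, sgn), , drop = FALSE]
      if (nrow(side) >= 2) {
        halves[[length(halves) + 1]] <-
          stats::approx(abs(side$s_um), side$kappa_s, xout = s_grid,
                        rule = 2)$y
      }
    }
  }
  mat <- do.call(cbind, halves)
  data.frame(s_um = s_grid,
             kappa_mean = rowMeans(mat),
             kappa_sd = apply(mat, 1, stats::sd),
             n = ncol(mat))
}

#' Curvature kymograph
#'
#' Assembles per-frame meridional-curvature profiles, each centred on its
#' pole, into a matrix ("heat map") of curvature versus signed meridional
#' distance and time.
#'
#' @param profiles list of per-frame data frames `s_um` (signed, 0 at the
#'   pole) and `kappa_s`; `NULL` entries mark frames with no pole.
#' @param times frame timestamps (min).
#' @param s_grid signed common grid (default symmetric, 121 points over the
#'   smallest common span).
#' @return An object of class `curvature_kymograph`: list with `kappa`
#'   (matrix s x t), `s_um`, `time_min`, `missing` (logical per frame).
#' @export
curvature_kymograph <- function(profiles, times = seq_along(profiles),
                                s_grid = NULL) {
  ok <- !vapply(profiles, is.null, TRUE)
  if (is.null(s_grid)) {
    smax <- min(vapply(profiles[ok], function(p) min(max(p$s_um), -min(p$s_um)), 0))
    s_grid <- seq(-smax, smax, length.out = 121)
  }
  mat <- matrix(NA_real_, nrow = length(s_grid), ncol = length(profiles))
  for (j in which(ok)) {
    p <- profiles[[j]]
    mat[, j] <- stats::approx(p$s_um, p$kappa_s, xout = s_grid, rule = 2)$y
  }
  structure(list(kappa = mat, s_um = s_grid, time_min = times,
                 missing = !ok),
            class = "curvature_kymograph")
}

#' @export
print.curvature_kymograph <- function(x, ...) {
  cat(sprintf("curvature_kymograph: %d s-points x %d frames (%d missing)\n",
              nrow(x$kappa), ncol(x$kappa), sum(x$missing)))
  invisible(x)
}

#' Render a curvature kymograph to PNG
#' @param kymo a [curvature_kymograph()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_kymograph <- function(kymo, path) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(x = kymo$time_min, y = kymo$s_um, z = t(kymo$kappa),
                  xlab = "time (min)", ylab = "s (um)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "meridional curvature (1/um)")
  invisible(path)
}
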