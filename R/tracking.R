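# Outline tracking on image stacks: anchor points of a spline contour are
# moved in small orthogonal steps; steps that increase the closed-contour
# intensity integral are kept, others rejected.

# bilinear interpolation of image values at (x, y) pixel coordinates
# (0-based, x = column, y = row); clamps to the image border.
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1); y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# intensity integral over the local stretch of contour around anchor i
# (polyline through anchors i-2..i+2, resampled finely)
.local_contour_integral <- function(img, px, py, i, per_seg = 8L) {
  n <- length(px)
  idx <- ((i - 3):(i + 1)) %% n + 1
  xs <- px[idx]; ys <- py[idx]
  x <- y <- numeric(0)
  for (k in seq_len(length(idx) - 1)) {
    tt <- seq(0, 1, length.out = per_seg + 1)[-1]
    x <- c(x, xs[k] + tt * (xs[k + 1] - xs[k]))
    y <- c(y, ys[k] + tt * (ys[k + 1] - ys[k]))
  }
  seg <- sqrt(diff(c(xs[1], x))^2 + diff(c(ys[1], y))^2)
  # average intensity per unit length: invariant on featureless images,
  # maximal when the contour rides the bright outline band
  sum(.bilinear(img, x, y) * seg) / sum(seg)
}

#' Track a cell outline through an image stack
#'
#' Starting from an initial anchor polygon near the first-frame outline,
#' each frame's contour is refined by hill climbing: every anchor is moved
#' in small steps orthogonal to the contour and a step is kept only when it
#' increases the intensity integral along the contour. The result of one
#' frame seeds the next.
#'
#' @param stack list of image matrices (rows = y, cols = x), or a 3-d array
#'   with frames along the third dimension.
#' @param initial_polygon a [planar_outline()] with the anchor points for
#'   frame 1 (typically a few tens of anchors).
#' @param step orthogonal step size in pixels.
#' @param max_sweeps maximum hill-climbing sweeps per frame.
#' @return A list of [planar_outline()]s, one per frame (anchor points).
#' @export
track_outlines <- function(stack, initial_polygon, step = 0.25,
                           max_sweeps = 60L) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  px <- initial_polygon$x; py <- initial_polygon$y
  pxs <- attr(initial_polygon, "pixel_size")
  out <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    img <- stack[[f]]
    nr <- nrow(img); nc <- ncol(img)
    for (sweep in seq_len(max_sweeps)) {
      moved <- FALSE
      n <- length(px)
      # normals from neighbouring anchors
      tx <- (px[c(2:n, 1)] - px[c(n, 1:(n - 1))])
      ty <- (py[c(2:n, 1)] - py[c(n, 1:(n - 1))])
      tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
      nx <- -ty / tl; ny <- tx / tl
      for (i in seq_len(n)) {
        base <- .local_contour_integral(img, px, py, i)
        for (sgn in c(1, -1)) {
          qx <- px; qy <- py
          qx[i] <- px[i] + sgn * step * nx[i]
          qy[i] <- py[i] + sgn * step * ny[i]
          if (qx[i] < 1 || qx[i] > nc - 2 || qy[i] < 1 || qy[i] > nr - 2)
            stop(sprintf("contour left the image at frame %d", f))
          cand <- .local_contour_integral(img, qx, qy, i)
          if (cand > base + 1e-9) {
            px <- qx; py <- qy; base <- cand; moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    out[[f]] <- planar_outline(px, py, pixel_size = pxs, frame = f)
  }
  out
}
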