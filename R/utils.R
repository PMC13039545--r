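# Internal geometry and array helpers shared across modules.

#' @importFrom stats rnorm runif rpois rlnorm sd median fft lm coef nls predict
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_retquant <- function(msg, class) {
  stop(structure(class = c(class, "retquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Signed area of a closed polygon (shoelace formula)
#' @param xy two-column matrix of vertices (not repeated at the end)
#' @return signed area; positive for counter-clockwise vertex order
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_perimeter <- function(xy) {
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Points strictly inside (or on) a polygon; wraps mgcv::in.out which treats
# the boundary as part of neither side consistently enough for pixel centers.
points_in_polygon <- function(pts, poly) {
  poly <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(as.matrix(poly), as.matrix(pts))
}

# Separable Gaussian blur of a 3D array, sigma given per axis in voxels.
# Axes with sigma == 0 are left untouched. Borders are zero-padded.
gauss_blur3 <- function(a, sigma_vox) {
  dims <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    n <- dims[ax]
    # band matrix acting along axis `ax`
    K <- matrix(0, n, n)
    for (off in seq(-half, half)) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1L & j <= n
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[off + half + 1L]
    }
    a <- apply_along(a, ax, function(m) K %*% m)
  }
  a
}

# Apply f to a matrix whose rows run along axis `ax`; f must return a matrix
# of the same shape.
apply_along <- function(a, ax, f) {
  dims <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = dims[ax])
  m <- f(m)
  aperm(array(m, dims[perm]), order(perm))
}

# Rasterize a line segment on a pixel grid (Bresenham-style supercover).
line_pixels <- function(x0, y0, x1, y1) {
  n <- max(2L, ceiling(2 * max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(round(x0 + t * (x1 - x0)), round(y0 + t * (y1 - y0)))
}

# Draw TRUE pixels into a logical matrix, clipping out-of-range coordinates.
set_pixels <- function(mask, px) {
  ok <- px[, 1] >= 1 & px[, 1] <= nrow(mask) & px[, 2] >= 1 & px[, 2] <= ncol(mask)
  mask[px[ok, , drop = FALSE]] <- TRUE
  mask
}

# Binary 3x3 dilation of a logical matrix.
dilate3x3 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    src_r <- max(1, 1 - dx):min(nr, nr - dx)
    src_c <- max(1, 1 - dy):min(nc, nc - dy)
    out[src_r + dx, src_c + dy] <- out[src_r + dx, src_c + dy] | m[src_r, src_c]
  }
  out
}
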