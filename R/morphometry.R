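#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative morphological thinning to a 1-pixel-wide skeleton, the
#' standard preprocessing before counting process crossings.
#'
#' @param mask logical matrix
#' @return logical matrix of the same size
#' @export
skeletonize <- function(mask) {
  m <- mask
  pad <- function(x) rbind(FALSE, cbind(FALSE, x, FALSE), FALSE)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(m)
      nr <- nrow(p); nc <- ncol(p)
      ctr <- p[2:(nr - 1), 2:(nc - 1)]
      # neighbours P2..P9 clockwise from north (row-1)
      P2 <- p[1:(nr - 2), 2:(nc - 1)]; P3 <- p[1:(nr - 2), 3:nc]
      P4 <- p[2:(nr - 1), 3:nc];       P5 <- p[3:nr, 3:nc]
      P6 <- p[3:nr, 2:(nc - 1)];       P7 <- p[3:nr, 1:(nc - 2)]
      P8 <- p[2:(nr - 1), 1:(nc - 2)]; P9 <- p[1:(nr - 2), 1:(nc - 2)]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (phase == 1L) {
        cond <- ctr & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- ctr & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Sholl intersection profile of a cell mask
#'
#' Counts, at increasing distances from the soma, the number of processes
#' crossed by concentric circles: for each radius, the circle is sampled
#' densely and every maximal contiguous arc of foreground pixels counts as
#' one intersection. Following the reference pipeline the mask is
#' skeletonized and then dilated by one pixel before counting, and the
#' starting radius is the minor diameter of the cell soma.
#'
#' @param mask logical matrix (one cell)
#' @param soma_center length-2 pixel coordinates of the soma centre
#' @param start_radius starting radius in um (the soma minor diameter)
#' @param step radius increment in um (default 1)
#' @param max_radius largest radius in um (default: to the field edge)
#' @param spacing_um um per pixel (isotropic; default 1)
#' @param preprocess skeletonize + dilate before counting (default TRUE;
#'   set FALSE if the mask is already a processed skeleton)
#' @return a `sholl_profile`: list with `radii` (um), `intersections`,
#'   `start_radius`, `step`
#' @export
sholl_profile <- function(mask, soma_center, start_radius, step = 1,
                          max_radius = NULL, spacing_um = 1,
                          preprocess = TRUE) {
  stopifnot(step > 0, start_radius >= 0)
  sc <- as.numeric(soma_center)
  if (sc[1] < 1 || sc[1] > nrow(mask) || sc[2] < 1 || sc[2] > ncol(mask))
    stop("soma centre must lie inside the image")
  if (preprocess) {
    if (!mask[round(sc[1]), round(sc[2])])
      stop("soma centre must lie on the cell mask")
    mask <- dilate3x3(skeletonize(mask))
  }
  if (is.null(max_radius)) {
    max_radius <- (max(nrow(mask), ncol(mask)) / 2) * spacing_um
  }
  radii <- seq(start_radius + step, max_radius, by = step)
  counts <- vapply(radii, function(r)
    count_arc_runs(mask, sc, r / spacing_um), 0L)
  structure(list(radii = radii, intersections = counts,
                 start_radius = start_radius, step = step),
            class = "sholl_profile")
}

# Number of maximal foreground arc runs on the circle of radius r (pixels),
# computed exactly: for every foreground pixel near the circle, the set of
# angles whose circle point falls into that pixel (half-open [-0.5, 0.5)
# pixel cells) is a union of arcs obtained by intersecting the cos- and
# sin-band angular intervals; the run count is the number of connected
# components of the union of all foreground arcs on the circle.
count_arc_runs <- function(mask, center, r_px) {
  if (r_px <= 0) return(0L)
  cand <- which(mask, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0L)
  d <- sqrt((cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2)
  near <- abs(d - r_px) <= sqrt(0.5) + 1e-9
  cand <- cand[near, , drop = FALSE]
  if (nrow(cand) == 0L) return(0L)
  arcs <- list()
  for (k in seq_len(nrow(cand))) {
    ax <- cos_band_arcs((cand[k, 1] - 0.5 - center[1]) / r_px,
                        (cand[k, 1] + 0.5 - center[1]) / r_px, sine = FALSE)
    ay <- cos_band_arcs((cand[k, 2] - 0.5 - center[2]) / r_px,
                        (cand[k, 2] + 0.5 - center[2]) / r_px, sine = TRUE)
    arcs <- c(arcs, intersect_arcs(ax, ay))
  }
  if (length(arcs) == 0L) return(0L)
  iv <- do.call(rbind, arcs)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  # merge arcs that touch (shared pixel boundaries give exact endpoint ties)
  eps <- 1e-9
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    last <- nrow(merged)
    if (iv[k, 1] <= merged[last, 2] + eps) {
      merged[last, 2] <- max(merged[last, 2], iv[k, 2])
    } else merged <- rbind(merged, iv[k, , drop = FALSE])
  }
  n_runs <- nrow(merged)
  # wrap-around: first arc starting at 0 joins a last arc ending at 2 pi
  if (n_runs > 1 && merged[1, 1] <= eps && merged[n_runs, 2] >= 2 * pi - eps)
    n_runs <- n_runs - 1L
  if (n_runs == 1 && merged[1, 1] <= eps && merged[1, 2] >= 2 * pi - eps)
    return(1L)
  as.integer(n_runs)
}

# Angular intervals (within [0, 2 pi)) where cos(theta) (or sin) lies in
# [lo, hi); returns a list of [start, end] rows, possibly split at 0/2pi.
cos_band_arcs <- function(lo, hi, sine = FALSE) {
  lo <- max(-1, min(1, lo)); hi <- max(-1, min(1, hi))
  if (hi <= lo) return(list())
  if (!sine) {
    # cos in [lo, hi]: theta in [acos(hi), acos(lo)] and its reflection
    a1 <- c(acos(hi), acos(lo))
    a2 <- c(2 * pi - acos(lo), 2 * pi - acos(hi))
    raw <- list(a1, a2)
  } else {
    # sin in [lo, hi]: theta in [asin(lo), asin(hi)] and [pi - asin(hi), pi - asin(lo)]
    a1 <- c(asin(lo), asin(hi))
    a2 <- c(pi - asin(hi), pi - asin(lo))
    raw <- list(a1, a2)
  }
  out <- list()
  for (a in raw) {
    if (a[2] <= a[1] + 1e-15) next
    a <- a %% (2 * pi)
    if (a[2] <= a[1]) {  # wrapped
      if (a[1] < 2 * pi) out <- c(out, list(c(a[1], 2 * pi)))
      if (a[2] > 0) out <- c(out, list(c(0, a[2])))
    } else out <- c(out, list(a))
  }
  out
}

intersect_arcs <- function(as1, as2) {
  out <- list()
  for (u in as1) for (v in as2) {
    lo <- max(u[1], v[1]); hi <- min(u[2], v[2])
    if (hi > lo) out <- c(out, list(c(lo, hi)))
  }
  out
}

#' Fit a log-normal curve to a Sholl profile and derive the branching span
#'
#' Least-squares fit of `N(r) = A * exp(-(ln r - mu)^2 / (2 sigma^2))` to
#' the intersection profile. The maximal branching span is the distal
#' radius at which the fitted curve falls to 50% of its peak:
#' `exp(mu + sigma * sqrt(2 ln 2))`. The proximal 50% crossing and the
#' full width between crossings are also reported.
#'
#' @param profile a [sholl_profile()] (or list with `radii`,
#'   `intersections`)
#' @return a `sholl_fit`: list with `A`, `mu`, `sigma`, `branching_span`,
#'   `span_proximal`, `full_width`, `converged`; on an all-zero profile or
#'   a failed fit, `converged = FALSE` and the spans are `NA`
#' @export
fit_sholl_lognormal <- function(profile) {
  r <- profile$radii
  y <- profile$intersections
  keep <- r > 0
  r <- r[keep]; y <- y[keep]
  fail <- list(A = NA_real_, mu = NA_real_, sigma = NA_real_,
               branching_span = NA_real_, span_proximal = NA_real_,
               full_width = NA_real_, converged = FALSE)
  class(fail) <- "sholl_fit"
  if (sum(y > 0) < 4L) return(fail)
  i0 <- which.max(y)
  start <- list(A = max(y), mu = log(r[i0]), sigma = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(log(r) - mu)^2 / (2 * sigma^2)),
                      start = start, control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- coef(fit)
  sigma <- abs(cf[["sigma"]])
  w <- sigma * sqrt(2 * log(2))
  out <- list(A = cf[["A"]], mu = cf[["mu"]], sigma = sigma,
              branching_span = exp(cf[["mu"]] + w),
              span_proximal = exp(cf[["mu"]] - w),
              full_width = exp(cf[["mu"]] + w) - exp(cf[["mu"]] - w),
              converged = TRUE)
  class(out) <- "sholl_fit"
  out
}

#' Circularity index of a region
#'
#' `4 * pi * area / perimeter^2`: 1.0 for a perfect circle, approaching 0
#' for increasingly elongated shapes. Polygon input is measured
#' analytically; mask input is polygonized first (marching-squares outer
#' contour), which avoids the downward bias of pixel-edge perimeters.
#'
#' @param region n x 2 polygon vertex matrix, or a logical mask matrix
#' @return circularity index
#' @export
circularity <- function(region) {
  if (is.logical(region)) {
    poly <- mask_contour(region)
    if (is.null(poly)) stop("empty mask: circularity undefined")
  } else {
    poly <- as.matrix(region)
    if (nrow(poly) < 3) stop("degenerate region: circularity undefined")
  }
  per <- polygon_perimeter(poly)
  if (per <= 0) stop("zero perimeter: circularity undefined")
  4 * pi * abs(polygon_area(poly)) / per^2
}

# Outer contour of a mask as a marching-squares polygon at level 0.5.
# The binary image is lightly smoothed (3x3 box, two passes) first so the
# half-level contour sits at the sub-pixel edge position instead of on the
# pixel staircase, which would bias perimeters ~6% high. Returns the
# contour of largest enclosed area, or NULL for an empty mask.
mask_contour <- function(mask, smooth_passes = 2L) {
  if (!any(mask)) return(NULL)
  pad <- 2L + smooth_passes
  z <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  z[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask * 1
  for (i in seq_len(smooth_passes)) z <- box_smooth3(z)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)) - pad - 0.5,
                                y = seq_len(ncol(z)) - pad - 0.5, z = z, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  areas <- vapply(cl, function(ct) abs(polygon_area(cbind(ct$x, ct$y))), 0)
  ct <- cl[[which.max(areas)]]
  cbind(ct$x, ct$y)
}

# 3x3 box filter of a numeric matrix (zero boundary).
box_smooth3 <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  shift <- function(m, dx, dy) {
    out <- matrix(0, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  acc <- matrix(0, nr, nc)
  for (dx in -1:1) for (dy in -1:1) acc <- acc + shift(z, dx, dy)
  acc / 9
}

#' Morphometry of an epithelial mosaic label image
#'
#' Measures every labeled cell of a segmented mosaic: area, perimeter,
#' best-fit ellipse axes (from the second moments of the pixel set),
#' circularity, and the number of neighbors (cells sharing at least one
#' pixel edge of boundary contact; diagonal-only contact does not count).
#' Cells touching the field edge are flagged `is_border` and excluded from
#' neighbor statistics and from the interior cell density.
#'
#' @param labels integer matrix; 0 = background, other values = cell ids
#' @param spacing_um um per pixel (isotropic)
#' @return list with `cells` (data frame: `id`, `area_um2`,
#'   `perimeter_um`, `major_um`, `minor_um`, `circularity`, `neighbors`,
#'   `is_border`), `density_per_um2` (interior cells / field area),
#'   `neighbor_table` (count of interior cells per neighbor number)
#' @export
rpe_morphometry <- function(labels, spacing_um = 1) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (length(ids) == 0L) stop("no labeled cells")
  nr <- nrow(labels); nc <- ncol(labels)
  # contiguity check per label (4-connectivity)
  for (id in ids) {
    m <- labels == id
    comp <- connected_components(m, connectivity = 6)
    if (length(comp$clusters) != 1L)
      stop(sprintf("label %d is not contiguous", id))
  }
  # pixel-edge adjacency from row/column shifts
  pairs <- rbind(cbind(as.integer(labels[-nr, ]), as.integer(labels[-1, ])),
                 cbind(as.integer(labels[, -nc]), as.integer(labels[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] != 0L & pairs[, 2] != 0L,
                 , drop = FALSE]
  pairs <- unique(t(apply(pairs, 1, sort)))
  nb_count <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = max(ids))
  edge_ids <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
  cells <- do.call(rbind, lapply(ids, function(id) {
    m <- labels == id
    px <- which(m, arr.ind = TRUE)
    area <- nrow(px) * spacing_um^2
    poly <- mask_contour(m)
    per <- polygon_perimeter(poly) * spacing_um
    cm <- cov(px * spacing_um)
    ev <- eigen(cm, symmetric = TRUE)$values
    ev[ev < 0] <- 0
    data.frame(id = id, area_um2 = area, perimeter_um = per,
               major_um = 4 * sqrt(ev[1]), minor_um = 4 * sqrt(ev[2]),
               circularity = 4 * pi * (abs(polygon_area(poly)) * spacing_um^2) / per^2,
               neighbors = nb_count[id], is_border = id %in% edge_ids)
  }))
  interior <- !cells$is_border
  list(cells = cells,
       density_per_um2 = sum(interior) / (nr * nc * spacing_um^2),
       neighbor_table = table(cells$neighbors[interior]))
}
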