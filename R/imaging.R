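#' Moment-preserving (moments) auto-threshold
#'
#' Computes the bilevel threshold of a gray-level histogram under the
#' moment-preserving criterion: binarizing at the returned level, with the
#' two representative gray values chosen to match the first and second
#' moments exactly, preserves the first three gray-level moments of the
#' image as closely as the histogram discretization allows. Every
#' candidate level is evaluated: for threshold `t` the below-threshold
#' mass is `p0(t)`, the representative levels are
#' `z0 = m1 - sqrt(v (1-p0)/p0)` and `z1 = m1 + sqrt(v p0/(1-p0))`
#' (`v` the variance), and the score is the absolute third-moment
#' mismatch. The level with the smallest mismatch wins; when several
#' levels tie (an empty histogram valley), the middle of the tying run is
#' returned. This is the classical "Moments" auto-threshold used for
#' fluorescence binarization.
#'
#' @param counts numeric vector of histogram counts (typically 256 bins)
#' @param levels gray levels of the bins (default `0:(length(counts)-1)`)
#' @return the threshold gray level; binarize with `intensity > threshold`
#' @export
moments_threshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) > 0, all(counts >= 0), length(levels) == length(counts))
  total <- sum(counts)
  if (total <= 0) stop("histogram is empty")
  p <- counts / total
  m1 <- sum(p * levels); m2 <- sum(p * levels^2); m3 <- sum(p * levels^3)
  v <- m2 - m1^2
  if (v <= 0 || sum(counts > 0) < 2)
    stop_retquant("degenerate histogram: all mass at a single gray level",
                  "retquant_degenerate_histogram")
  p0 <- cumsum(p)
  q0 <- 1 - p0
  ok <- p0 > 0 & q0 > 0
  err <- rep(Inf, length(levels))
  z0 <- m1 - sqrt(v * q0[ok] / p0[ok])
  z1 <- m1 + sqrt(v * p0[ok] / q0[ok])
  err[ok] <- abs(p0[ok] * z0^3 + q0[ok] * z1^3 - m3)
  tol <- 1e-9 * (abs(m3) + 1)
  tied <- which(err <= min(err) + tol)
  levels[tied[ceiling(length(tied) / 2)]]
}

#' Binarize a stack channel at a threshold
#'
#' A voxel is foreground iff its intensity is strictly greater than the
#' threshold, so raising the threshold never adds voxels. The threshold is
#' computed once on the whole-stack histogram by default (volumes are
#' binarized globally); a per-slice variant is available via `scope`.
#'
#' @param x numeric array (or [image_stack] channel array)
#' @param threshold intensity cutoff
#' @param scope `"global_3d"` (one threshold for the volume) or
#'   `"per_slice"` (`threshold` must then be a vector, one per z-plane)
#' @return logical array of the same shape
#' @export
binarize <- function(x, threshold, scope = c("global_3d", "per_slice")) {
  scope <- match.arg(scope)
  if (scope == "global_3d") {
    stopifnot(length(threshold) == 1)
    return(x > threshold)
  }
  stopifnot(length(dim(x)) == 3L, length(threshold) == dim(x)[3])
  out <- array(FALSE, dim(x))
  for (z in seq_len(dim(x)[3])) out[, , z] <- x[, , z] > threshold[z]
  out
}

#' Histogram of stack intensities on a fixed number of bins
#'
#' Bins the intensity range into `n_bins` equal-width bins (ImageJ-style
#' 8-bit convention) and returns counts plus the bin-centre gray levels, in
#' the form [moments_threshold()] consumes.
#'
#' @param x numeric array
#' @param n_bins number of bins (default 256)
#' @return list with `counts` and `levels`
#' @export
intensity_histogram <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(list(counts = c(length(x), rep(0, n_bins - 1L)),
                                    levels = rep(rng[1], n_bins)))
  width <- diff(rng) / n_bins
  idx <- pmin(n_bins, floor((as.numeric(x) - rng[1]) / width) + 1L)
  list(counts = tabulate(idx, nbins = n_bins),
       levels = rng[1] + (seq_len(n_bins) - 0.5) * width)
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

#' Connected components of a binary volume
#'
#' Labels maximal connected voxel sets under 6-, 18- or 26-connectivity
#' (default 26, the ImageJ-style particle aggregation: blurred blobs in
#' diagonal contact are one physical cluster). Components are extracted
#' from the voxel adjacency graph.
#'
#' @param mask logical array (2D masks are treated as single-plane 3D)
#' @param connectivity 6, 18 or 26
#' @return a `cluster_set`: list with `clusters` (list of n x 3 voxel index
#'   matrices, 1-based), `labels` (integer array), and provenance fields
#'   `connectivity` and `threshold` (NA until set by the caller)
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (length(dim(mask)) == 2L) mask <- array(mask, c(dim(mask), 1L))
  stopifnot(length(dim(mask)) == 3L, is.logical(mask))
  dims <- dim(mask)
  fg <- which(mask)
  labels <- array(0L, dims)
  if (length(fg) == 0L) {
    return(structure(list(clusters = list(), labels = labels,
                          connectivity = connectivity, threshold = NA_real_),
                     class = "cluster_set"))
  }
  rank <- integer(prod(dims)); rank[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dims)
  offs <- neighbor_offsets(connectivity)
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    hit <- rank[lin] > 0L
    edges[[k]] <- cbind(which(ok)[hit], rank[lin[hit]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  clusters <- lapply(split(seq_along(fg), comp), function(ii) coords[ii, , drop = FALSE])
  names(clusters) <- NULL
  structure(list(clusters = clusters, labels = labels,
                 connectivity = connectivity, threshold = NA_real_),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (connectivity %d, threshold %s)\n",
              length(x$clusters), x$connectivity, format(x$threshold)))
  invisible(x)
}

#' Major diameter of a voxel cluster
#'
#' The 3D maximum Feret diameter over member-voxel centres in physical
#' units, plus one mean voxel pitch to account for the finite voxel
#' extent (a single-voxel cluster then reports one mean pitch rather than
#' zero, consistent with a physical particle of at least one voxel).
#'
#' @param voxels n x 3 matrix of 1-based voxel indices
#' @param spacing um per voxel (x, y, z)
#' @return diameter in um
#' @export
major_diameter <- function(voxels, spacing) {
  stopifnot(nrow(voxels) >= 1, length(spacing) == 3)
  pts <- voxel_centers_um(voxels, spacing)
  extent <- mean(spacing)
  if (nrow(pts) == 1L) return(extent)
  if (nrow(pts) > 1500L) pts <- pts[boundary_voxels(voxels), , drop = FALSE]
  max(stats::dist(pts)) + extent
}

# Voxels of a cluster with fewer than 6 face neighbours inside the cluster;
# the max pairwise distance is attained on this subset.
boundary_voxels <- function(voxels) {
  key <- paste(voxels[, 1], voxels[, 2], voxels[, 3])
  inside <- rep(0L, nrow(voxels))
  offs <- neighbor_offsets(6)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(voxels, 2, offs[k, ], `+`)
    inside <- inside + (paste(nb[, 1], nb[, 2], nb[, 3]) %in% key)
  }
  inside < 6L
}

#' Cluster diameter frequency distribution in 250-nm bins
#'
#' Groups cluster major diameters into left-closed right-open bins of
#' `bin_width` um starting at 0 and normalizes by the total number of
#' clusters. Also reports the fraction of clusters below a cutoff
#' (default 2 um).
#'
#' @param diameters vector of diameters (um), all >= 0
#' @param bin_width bin width in um (default 0.25, i.e. 250 nm)
#' @param cutoff_um report the fraction of clusters strictly below this
#' @return a `diameter_histogram`: list with `breaks`, `frequency`,
#'   `counts`, `n_total`, `modal_bin` (interval of the most frequent bin)
#'   and `fraction_below_cutoff`
#' @export
diameter_histogram <- function(diameters, bin_width = 0.25, cutoff_um = 2) {
  stopifnot(all(diameters >= 0))
  n <- length(diameters)
  if (n == 0L) {
    return(structure(list(breaks = numeric(0), frequency = numeric(0),
                          counts = integer(0), n_total = 0L,
                          modal_bin = c(NA_real_, NA_real_),
                          fraction_below_cutoff = NA_real_),
                     class = "diameter_histogram"))
  }
  n_bins <- max(1L, floor(max(diameters) / bin_width) + 1L)
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- pmin(n_bins, floor(diameters / bin_width) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  mb <- which.max(counts)
  structure(list(breaks = breaks, frequency = counts / n, counts = counts,
                 n_total = n, modal_bin = c(breaks[mb], breaks[mb + 1L]),
                 fraction_below_cutoff = mean(diameters < cutoff_um)),
            class = "diameter_histogram")
}

#' Nearest-neighbor distances between cluster centroids
#'
#' For each point, the Euclidean distance to its closest other point; the
#' mean NND is the granularity measure of the particle distribution. An
#' optional border edge correction excludes points that lie closer to the
#' window boundary than to their nearest neighbor, removing the upward
#' bias of finite windows.
#'
#' @param points n x d matrix of coordinates (um), n >= 2
#' @param window optional 2 x d matrix of `[lo, hi]` per dimension for the
#'   border correction
#' @param edge_correction `"none"` or `"border"`
#' @return list with `nnd` (per point, uncorrected), `mean` (over the
#'   points retained by the edge correction) and `retained` (logical)
#' @export
nearest_neighbor_distances <- function(points, window = NULL,
                                       edge_correction = c("none", "border")) {
  edge_correction <- match.arg(edge_correction)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L)
    stop_retquant("need at least 2 points for nearest-neighbor distances",
                  "retquant_insufficient_points")
  nnd <- numeric(n)
  block <- 512L
  for (i0 in seq(1L, n, by = block)) {
    ii <- i0:min(n, i0 + block - 1L)
    d2 <- matrix(0, length(ii), n)
    for (k in seq_len(ncol(points)))
      d2 <- d2 + outer(points[ii, k], points[, k], `-`)^2
    d2[cbind(seq_along(ii), ii)] <- Inf
    nnd[ii] <- sqrt(apply(d2, 1, min))
  }
  retained <- rep(TRUE, n)
  if (edge_correction == "border") {
    if (is.null(window)) stop("border correction requires a window")
    window <- as.matrix(window)
    db <- rep(Inf, n)
    for (k in seq_len(ncol(points)))
      db <- pmin(db, points[, k] - window[1, k], window[2, k] - points[, k])
    retained <- nnd <= db
  }
  list(nnd = nnd, mean = mean(nnd[retained]), retained = retained)
}

#' Fractional area covered by the particle extension boundary
#'
#' Encloses all foreground of a binarized Z-max projection (or an explicit
#' point set) in a concave boundary polygon and reports its area as a
#' percentage of the region-of-interest area. `shrink = 0` gives the
#' convex hull; larger values tighten the boundary onto the points
#' (a k-nearest-neighbor concave hull whose neighborhood size shrinks
#' log-linearly from all points at 0 to 3 at 1).
#'
#' @param x logical matrix (projection; foreground pixel centres are used)
#'   or an n x 2 matrix of points
#' @param roi polygon (m x 2) whose area is the denominator; for a
#'   projection the default is the full image rectangle
#' @param shrink boundary tightness in `[0, 1]`; default 0.5
#' @return list with `percent`, `boundary` (polygon), `area`, `roi_area`
#' @export
coverage_fraction <- function(x, roi = NULL, shrink = 0.5) {
  stopifnot(shrink >= 0, shrink <= 1)
  if (is.logical(x) && is.matrix(x)) {
    pts <- which(x, arr.ind = TRUE) - 0.5
    if (is.null(roi))
      roi <- cbind(c(0, nrow(x), nrow(x), 0), c(0, 0, ncol(x), ncol(x)))
  } else {
    pts <- as.matrix(x)
    if (is.null(roi)) stop("`roi` is required for point input")
  }
  roi_area <- abs(polygon_area(roi))
  if (roi_area <= 0) stop("ROI area must be positive")
  if (nrow(pts) == 0L)
    return(list(percent = 0, boundary = NULL, area = 0, roi_area = roi_area))
  if (nrow(pts) < 3L)
    return(list(percent = 0, boundary = pts, area = 0, roi_area = roi_area))
  hull <- concave_hull(pts, shrink)
  area <- abs(polygon_area(hull))
  list(percent = 100 * area / roi_area, boundary = hull, area = area,
       roi_area = roi_area)
}

#' Concave hull of a point set
#'
#' k-nearest-neighbor concave hull: a gift-wrapping walk that at each step
#' chooses, among the k nearest unused points, the one making the sharpest
#' admissible right turn, rejecting candidates that would intersect the
#' boundary built so far; k is escalated until the walk closes with every
#' point enclosed. `shrink = 0` returns the convex hull exactly.
#'
#' @param pts n x 2 matrix
#' @param shrink in `[0, 1]`, mapped log-linearly to the neighborhood size
#' @return polygon vertex matrix (not closed)
#' @export
concave_hull <- function(pts, shrink = 0.5) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (shrink == 0 || n <= 4L) {
    return(pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE])
  }
  k0 <- max(3L, ceiling(exp((1 - shrink) * log(n - 1) + shrink * log(3))))
  for (k in unique(pmin(n - 1L, c(k0, k0 + 2L, k0 + 4L, k0 + 8L, k0 + 16L, n - 1L)))) {
    h <- knn_hull_walk(pts, k)
    if (!is.null(h)) return(h)
  }
  pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
}

knn_hull_walk <- function(pts, k, max_steps = 4L * nrow(pts)) {
  n <- nrow(pts)
  start <- which.min(pts[, 2] * 1e6 + pts[, 1])
  hull <- start
  used <- rep(FALSE, n)
  cur <- start; prev_ang <- pi  # incoming direction: pointing left
  for (step in seq_len(max_steps)) {
    d2 <- (pts[, 1] - pts[cur, 1])^2 + (pts[, 2] - pts[cur, 2])^2
    d2[cur] <- Inf
    cand <- order(d2)[seq_len(min(k, n - 1L))]
    cand <- cand[!used[cand] | (cand == start & length(hull) > 2L)]
    if (length(cand) == 0L) return(NULL)
    ang <- atan2(pts[cand, 2] - pts[cur, 2], pts[cand, 1] - pts[cur, 1])
    turn <- (prev_ang - ang) %% (2 * pi)  # clockwise turn from reversed incoming
    cand <- cand[order(-turn)]
    nxt <- NA_integer_
    for (cc in cand) {
      if (!self_intersects(pts, hull, cur, cc, start)) { nxt <- cc; break }
    }
    if (is.na(nxt)) return(NULL)
    if (nxt == start) {
      hull_pts <- pts[hull, , drop = FALSE]
      inside <- points_in_polygon(pts, hull_pts)
      on_hull <- seq_len(n) %in% hull
      if (all(inside | on_hull)) return(hull_pts) else return(NULL)
    }
    used[nxt] <- TRUE
    prev_ang <- atan2(pts[cur, 2] - pts[nxt, 2], pts[cur, 1] - pts[nxt, 1])
    hull <- c(hull, nxt)
    cur <- nxt
  }
  NULL
}

self_intersects <- function(pts, hull, cur, nxt, start) {
  if (length(hull) < 3L) return(FALSE)
  a <- pts[cur, ]; b <- pts[nxt, ]
  last <- if (nxt == start) 2L else 1L
  for (i in seq_len(length(hull) - 1L - last)) {
    p <- pts[hull[i], ]; q <- pts[hull[i + 1L], ]
    if (segments_cross(a, b, p, q)) return(TRUE)
  }
  FALSE
}

segments_cross <- function(a, b, p, q) {
  o <- function(u, v, w) sign((v[1] - u[1]) * (w[2] - u[2]) - (v[2] - u[2]) * (w[1] - u[1]))
  o1 <- o(a, b, p); o2 <- o(a, b, q); o3 <- o(p, q, a); o4 <- o(p, q, b)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

#' Fraction of clusters internalized by a compartment
#'
#' A cluster counts as inside the compartment iff its centroid voxel (the
#' rounded mean of its member voxel indices) lies in the compartment mask,
#' making compartment counts partition-exact.
#'
#' @param clusters a `cluster_set` from [connected_components()]
#' @param mask logical array, same geometry as the segmented stack
#' @return list with `percent`, `n_inside`, `n_total`
#' @export
internalization_fraction <- function(clusters, mask) {
  if (length(dim(mask)) == 2L) mask <- array(mask, c(dim(mask), 1L))
  if (length(clusters$clusters) == 0L)
    stop_retquant("no clusters: internalization fraction undefined",
                  "retquant_undefined_fraction")
  stopifnot(identical(dim(clusters$labels), dim(mask)))
  inside <- vapply(clusters$clusters, function(v) {
    c0 <- pmin(pmax(1L, as.integer(round(colMeans(v)))), dim(mask))
    mask[matrix(c0, 1)]
  }, logical(1))
  list(percent = 100 * mean(inside), n_inside = sum(inside),
       n_total = length(inside))
}

#' Manders split colocalization coefficients
#'
#' Area mode (default, matching overlap of binarized immunoreactive
#' areas): `M1 = |A n B| / |A|`, `M2 = |A n B| / |B|`. Intensity mode:
#' the classical intensity-weighted split coefficients, `M1` the fraction
#' of channel-A intensity lying where B is positive and vice versa. Empty
#' sides yield an `NA` coefficient flagged in `undefined`.
#'
#' @param maskA,maskB logical arrays of identical geometry
#' @param mode `"area"` or `"intensity"`
#' @param intensitiesA,intensitiesB intensity arrays (intensity mode only)
#' @return list with `M1`, `M2`, `mode`, `undefined` (character vector)
#' @export
manders_coefficients <- function(maskA, maskB, mode = c("area", "intensity"),
                                 intensitiesA = NULL, intensitiesB = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(maskA), dim(maskB)))
  overlap <- maskA & maskB
  undefined <- character(0)
  if (mode == "area") {
    nA <- sum(maskA); nB <- sum(maskB)
    M1 <- if (nA > 0) sum(overlap) / nA else { undefined <- c(undefined, "M1"); NA_real_ }
    M2 <- if (nB > 0) sum(overlap) / nB else { undefined <- c(undefined, "M2"); NA_real_ }
  } else {
    if (is.null(intensitiesA) || is.null(intensitiesB))
      stop("intensity mode requires both intensity arrays")
    sA <- sum(intensitiesA[maskA]); sB <- sum(intensitiesB[maskB])
    M1 <- if (sA > 0) sum(intensitiesA[overlap]) / sA else { undefined <- c(undefined, "M1"); NA_real_ }
    M2 <- if (sB > 0) sum(intensitiesB[overlap]) / sB else { undefined <- c(undefined, "M2"); NA_real_ }
  }
  list(M1 = M1, M2 = M2, mode = mode, undefined = undefined)
}

#' Integrated density over regions of interest on a sum projection
#'
#' Projects the stack by summing over z and accumulates the projected
#' intensity of every pixel whose centre falls inside each ROI polygon;
#' reports per-ROI integrated densities and their mean (the astroglial
#' immunoreactivity readout averages 6 ROIs per field).
#'
#' @param x numeric array (3D; a 2D matrix is used as-is)
#' @param rois list of polygons (m x 2, pixel coordinates, x then y)
#' @return list with `per_roi` and `mean`
#' @export
integrated_density <- function(x, rois) {
  stopifnot(length(rois) >= 1)
  proj <- if (length(dim(x)) == 3L) apply(x, c(1, 2), sum) else x
  nr <- nrow(proj); nc <- ncol(proj)
  centers <- as.matrix(expand.grid(x = seq_len(nr) - 0.5, y = seq_len(nc) - 0.5))
  vals <- vapply(rois, function(poly) {
    poly <- as.matrix(poly)
    if (any(poly[, 1] < 0 | poly[, 1] > nr | poly[, 2] < 0 | poly[, 2] > nc))
      stop("ROI polygon extends outside the image")
    sum(proj[points_in_polygon(centers, poly)])
  }, 0)
  list(per_roi = vals, mean = mean(vals))
}

#' Segment nanoparticle clusters in a stack channel
#'
#' The standard particle pipeline: moments auto-threshold on the
#' whole-stack 256-bin histogram, global binarization, connected
#' components, then per-cluster centroid (um) and major diameter.
#'
#' @param stack an [image_stack]
#' @param channel channel name (default the first)
#' @param connectivity component connectivity (default 26)
#' @param threshold optional fixed threshold overriding the auto-threshold
#' @return a `cluster_set` augmented with `table`, a data frame of
#'   `id`, `n_voxels`, centroid coordinates (um) and `diameter_um`
#' @export
segment_particles <- function(stack, channel = NULL, connectivity = 26,
                              threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  channel <- channel %||% names(stack$channels)[1]
  vol <- stack$channels[[channel]]
  if (is.null(threshold)) {
    h <- intensity_histogram(vol)
    threshold <- moments_threshold(h$counts, h$levels)
  }
  cs <- connected_components(binarize(vol, threshold), connectivity)
  cs$threshold <- threshold
  cs$channel <- channel
  if (length(cs$clusters) > 0) {
    cen <- t(vapply(cs$clusters, function(v)
      colMeans(voxel_centers_um(v, stack$spacing)), numeric(3)))
    cs$table <- data.frame(
      id = seq_along(cs$clusters),
      n_voxels = vapply(cs$clusters, nrow, 0L),
      cx_um = cen[, 1], cy_um = cen[, 2], cz_um = cen[, 3],
      diameter_um = vapply(cs$clusters, major_diameter, 0, spacing = stack$spacing))
  } else {
    cs$table <- data.frame(id = integer(0), n_voxels = integer(0),
                           cx_um = numeric(0), cy_um = numeric(0),
                           cz_um = numeric(0), diameter_um = numeric(0))
  }
  cs
}
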