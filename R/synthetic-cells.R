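#' Generate synthetic microglia masks with morphological ground truth
#'
#' Renders either ramified (quiescent) or ameboid (activated) microglia on
#' a binary pixel grid. Ramified cells are a soma disk plus a random binary
#' tree of 1-pixel-wide processes: each primary branch leaves the soma rim
#' at a random angle and extends in segments that may turn and bifurcate.
#' The true branch span of a cell is the maximum Euclidean distance from a
#' branch root (on the soma rim) to any tip of its tree. Ameboid cells are
#' near-circular blobs whose outline is a smoothly perturbed circle; their
#' true circularity is computed exactly from the generating polygon.
#'
#' @param n_cells number of cells (>= 1)
#' @param state `"ramified"` or `"ameboid"`
#' @param field_px field side length in pixels (square field)
#' @param soma_radius_px soma (or blob) radius in pixels
#' @param n_primary ramified: number of primary branches
#' @param branch_length_px ramified: total straight length of a primary
#'   branch (pixels); with `turn_sd = 0`, `branch_prob = 0` the true span
#'   equals this length exactly
#' @param n_segments ramified: segments per branch
#' @param turn_sd ramified: SD of the per-segment heading change (radians)
#' @param branch_prob ramified: probability that a segment end bifurcates
#' @param blob_irregularity ameboid: relative amplitude of the outline
#'   perturbation (0 gives a perfect disk, ground-truth circularity 1)
#' @param primary_angles optional fixed primary-branch angles (radians),
#'   overriding the random draw; useful for constructing reference cells
#' @param seed integer seed
#' @return list with `mask` (logical matrix), `truth` (data frame: `id`,
#'   soma centre in px, `state`, `span_px` for ramified cells,
#'   `circularity` for ameboid cells)
#' @export
generate_microglia <- function(n_cells, state = c("ramified", "ameboid"),
                               field_px = 256L, soma_radius_px = 6,
                               n_primary = 5L, branch_length_px = 40,
                               n_segments = 4L, turn_sd = 0.3, branch_prob = 0.25,
                               blob_irregularity = 0.15, primary_angles = NULL,
                               seed = 1L) {
  state <- match.arg(state)
  stopifnot(n_cells >= 1)
  withr::with_seed(seed, {
    mask <- matrix(FALSE, field_px, field_px)
    reach <- soma_radius_px +
      if (state == "ramified") branch_length_px * 1.2 else soma_radius_px * 2
    centers <- place_somata(n_cells, field_px, reach, min_sep = 2.2 * reach)
    span <- circ <- rep(NA_real_, n_cells)
    for (i in seq_len(n_cells)) {
      if (state == "ramified") {
        out <- draw_ramified(mask, centers[i, ], soma_radius_px, n_primary,
                             branch_length_px, n_segments, turn_sd, branch_prob,
                             primary_angles)
        mask <- out$mask; span[i] <- out$span
      } else {
        out <- draw_ameboid(mask, centers[i, ], soma_radius_px * 2,
                            blob_irregularity)
        mask <- out$mask; circ[i] <- out$circularity
      }
    }
    truth <- data.frame(id = seq_len(n_cells), cx_px = centers[, 1],
                        cy_px = centers[, 2], state = state,
                        span_px = span, circularity = circ,
                        stringsAsFactors = FALSE)
    list(mask = mask, truth = truth)
  })
}

place_somata <- function(n, field, reach, min_sep, max_tries = 500L) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- runif(2, 1 + reach, field - reach)
      if (1 + reach > field - reach)
        stop_retquant("field too small for requested cell reach",
                      "retquant_packing_error")
      if (i == 1L ||
          min(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE], 2, p)^2))) >= min_sep) {
        centers[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop_retquant(sprintf("could not place soma %d of %d without overlap", i, n),
                    "retquant_packing_error")
  }
  centers
}

draw_disk <- function(mask, center, r) {
  xr <- max(1, floor(center[1] - r)):min(nrow(mask), ceiling(center[1] + r))
  yr <- max(1, floor(center[2] - r)):min(ncol(mask), ceiling(center[2] + r))
  g <- as.matrix(expand.grid(x = xr, y = yr))
  inside <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 <= r^2
  mask[g[inside, , drop = FALSE]] <- TRUE
  mask
}

draw_ramified <- function(mask, center, r0, n_primary, total_len, n_segments,
                          turn_sd, branch_prob, primary_angles = NULL) {
  mask <- draw_disk(mask, center, r0)
  seg_len <- total_len / n_segments
  span2 <- 0
  angles <- primary_angles %||% runif(n_primary, 0, 2 * pi)
  for (a in angles) {
    root <- center + r0 * c(cos(a), sin(a))
    # stack of growth fronts: position, heading, remaining segments
    fronts <- list(list(p = root, h = a, left = n_segments))
    while (length(fronts) > 0) {
      fr <- fronts[[1]]; fronts <- fronts[-1]
      if (fr$left == 0L) {
        span2 <- max(span2, sum((fr$p - root)^2))
        next
      }
      h <- fr$h + if (turn_sd > 0) rnorm(1, sd = turn_sd) else 0
      q <- fr$p + seg_len * c(cos(h), sin(h))
      mask <- set_pixels(mask, line_pixels(fr$p[1], fr$p[2], q[1], q[2]))
      fronts <- c(fronts, list(list(p = q, h = h, left = fr$left - 1L)))
      if (branch_prob > 0 && fr$left > 1L && runif(1) < branch_prob) {
        hb <- h + sample(c(-1, 1), 1) * (pi / 5)
        fronts <- c(fronts, list(list(p = q, h = hb, left = fr$left - 1L)))
      }
    }
  }
  list(mask = mask, span = sqrt(span2))
}

draw_ameboid <- function(mask, center, r, irregularity, n_vertices = 1024L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  rad <- rep(r, n_vertices)
  if (irregularity > 0) {
    for (m in 2:5) {
      rad <- rad + r * irregularity / m * cos(m * theta + runif(1, 0, 2 * pi))
    }
  }
  poly <- cbind(center[1] + rad * cos(theta), center[2] + rad * sin(theta))
  circ <- 4 * pi * abs(polygon_area(poly)) / polygon_perimeter(poly)^2
  xr <- max(1, floor(min(poly[, 1]))):min(nrow(mask), ceiling(max(poly[, 1])))
  yr <- max(1, floor(min(poly[, 2]))):min(ncol(mask), ceiling(max(poly[, 2])))
  g <- as.matrix(expand.grid(x = xr, y = yr))
  inside <- points_in_polygon(g, poly)
  mask[g[inside, , drop = FALSE]] <- TRUE
  list(mask = mask, circularity = circ)
}

#' Generate a synthetic epithelial mosaic as a label image
#'
#' Builds a Voronoi tessellation of seed points arranged on a jittered
#' hexagonal lattice (or uniformly at random), rasterized so every pixel
#' carries the label of its nearest seed. Ground-truth neighbor counts come
#' from the geometric Voronoi adjacency of the seeds (two cells are
#' neighbors when their bisector contributes an edge inside the field),
#' computed independently of the rasterization.
#'
#' @param n_cells requested number of cells (>= 7). For the hexagonal
#'   arrangement the count is rounded up to a full `rows x cols` lattice;
#'   the realized count is `nrow(truth)`.
#' @param jitter SD of the Gaussian seed displacement, in units of the
#'   lattice pitch; 0 gives a perfect hexagonal mosaic
#' @param field_px field side length (pixels, square)
#' @param arrangement `"hex"` (jittered lattice) or `"uniform"` (random
#'   seeds, a Poisson-Voronoi mosaic)
#' @param seed integer seed
#' @return list with `labels` (integer matrix, every pixel labeled),
#'   `seeds` (n x 2 matrix), `truth` (data frame: `id`, seed coordinates,
#'   `n_neighbors`, `is_border`), and `density_per_px2`
#' @export
generate_rpe_mosaic <- function(n_cells, jitter = 0.1, field_px = 256L,
                                arrangement = c("hex", "uniform"), seed = 1L) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_cells >= 7)
  withr::with_seed(seed, {
    if (arrangement == "hex") {
      # pitch so that rows x cols covers the field with ~n_cells sites
      pitch <- sqrt(field_px^2 / n_cells / (sqrt(3) / 2))
      cols <- max(3L, ceiling(field_px / pitch))
      rows <- max(3L, ceiling(field_px / (pitch * sqrt(3) / 2)))
      ix <- rep(seq_len(cols), rows)
      iy <- rep(seq_len(rows), each = cols)
      x <- (ix - 0.5 + 0.5 * (iy %% 2)) * (field_px / cols)
      y <- (iy - 0.5) * (field_px / rows)
      seeds <- cbind(x, y)
      if (jitter > 0) seeds <- seeds + matrix(rnorm(length(seeds), sd = jitter * pitch),
                                              ncol = 2)
    } else {
      seeds <- cbind(runif(n_cells, 0, field_px), runif(n_cells, 0, field_px))
    }
    n <- nrow(seeds)
    labels <- rasterize_voronoi(seeds, field_px)
    adj <- voronoi_adjacency(seeds, field_px)
    n_neighbors <- tabulate(c(adj[, 1], adj[, 2]), nbins = n)
    border <- voronoi_border_cells(seeds, field_px)
    truth <- data.frame(id = seq_len(n), x_px = seeds[, 1], y_px = seeds[, 2],
                        n_neighbors = n_neighbors, is_border = border)
    list(labels = labels, seeds = seeds, truth = truth,
         density_per_px2 = n / field_px^2)
  })
}

rasterize_voronoi <- function(seeds, field, block = 32L) {
  labels <- matrix(0L, field, field)
  ys <- seq_len(field) - 0.5
  for (x0 in seq(1L, field, by = block)) {
    xs <- x0:min(field, x0 + block - 1L) - 0.5
    g <- as.matrix(expand.grid(x = xs, y = ys))
    d2 <- outer(g[, 1], seeds[, 1], `-`)^2 + outer(g[, 2], seeds[, 2], `-`)^2
    labels[x0:min(field, x0 + block - 1L), ] <-
      matrix(max.col(-d2, ties.method = "first"), nrow = length(xs))
  }
  labels
}

# Geometric Voronoi adjacency: sample each candidate pair's perpendicular
# bisector inside the field and test whether the two seeds are jointly the
# nearest pair anywhere on it.
voronoi_adjacency <- function(seeds, field, n_samples = 600L) {
  n <- nrow(seeds)
  d <- as.matrix(stats::dist(seeds))
  cutoff <- 4 * sqrt(field^2 / n)  # pairs farther than this cannot touch
  pairs <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    mid <- (seeds[i, ] + seeds[j, ]) / 2
    dir <- (seeds[j, ] - seeds[i, ]) / d[i, j]
    perp <- c(-dir[2], dir[1])
    # a shared edge lies within ~one cell diameter of the midpoint; sample
    # densely there so short Voronoi edges are not missed
    t <- seq(-cutoff, cutoff, length.out = n_samples)
    pts <- cbind(mid[1] + t * perp[1], mid[2] + t * perp[2])
    inside <- pts[, 1] >= 0 & pts[, 1] <= field & pts[, 2] >= 0 & pts[, 2] <= field
    if (!any(inside)) next
    pts <- pts[inside, , drop = FALSE]
    d2 <- outer(pts[, 1], seeds[, 1], `-`)^2 + outer(pts[, 2], seeds[, 2], `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    # bisector points are equidistant from i and j; adjacency holds if one
    # of them is the strict nearest among all *other* seeds there
    keep[k] <- any(nearest == i | nearest == j)
  }
  pairs[keep, , drop = FALSE]
}

# Cells whose Voronoi region touches the field boundary.
voronoi_border_cells <- function(seeds, field, n_samples = 400L) {
  t <- seq(0, field, length.out = n_samples)
  edge <- rbind(cbind(t, 0), cbind(t, field), cbind(0, t), cbind(field, t))
  d2 <- outer(edge[, 1], seeds[, 1], `-`)^2 + outer(edge[, 2], seeds[, 2], `-`)^2
  border_ids <- unique(max.col(-d2, ties.method = "first"))
  seq_len(nrow(seeds)) %in% border_ids
}
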