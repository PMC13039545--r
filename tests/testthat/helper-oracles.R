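# Independent brute-force oracles used to cross-check the package
# implementations. Each takes a deliberately different computational route
# from the function it validates.

# Moment-preserving threshold by per-level 1D root finding: for each
# candidate level, eliminate z1 linearly from the first-moment equation and
# solve the second-moment equation for z0 with uniroot, then score the
# third-moment mismatch. Midpoint-of-tie-run selection as documented.
oracle_moments_threshold <- function(counts, levels = seq_along(counts) - 1) {
  p <- counts / sum(counts)
  m1 <- sum(p * levels); m2 <- sum(p * levels^2); m3 <- sum(p * levels^3)
  v <- m2 - m1^2
  cum <- cumsum(p)
  errs <- vapply(seq_along(levels), function(t) {
    p0 <- cum[t]
    if (p0 <= 0 || p0 >= 1) return(Inf)
    g <- function(z0) {
      z1 <- (m1 - p0 * z0) / (1 - p0)
      p0 * z0^2 + (1 - p0) * z1^2 - m2
    }
    lo <- m1 - 10 * sqrt(v / min(p0, 1 - p0)) - 1
    z0 <- stats::uniroot(g, c(lo, m1), tol = 1e-12)$root
    z1 <- (m1 - p0 * z0) / (1 - p0)
    abs(p0 * z0^3 + (1 - p0) * z1^3 - m3)
  }, 0)
  tol <- 1e-9 * (abs(m3) + 1)
  tied <- which(errs <= min(errs) + tol)
  levels[tied[ceiling(length(tied) / 2)]]
}

# Recursive flood fill over an explicit neighbour stencil.
oracle_flood_fill <- function(mask, connectivity = 26) {
  if (length(dim(mask)) == 2L) mask <- array(mask, c(dim(mask), 1L))
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  fg <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(fg))) {
    if (lab[fg[s, , drop = FALSE]] != 0L) next
    nxt <- nxt + 1L
    queue <- fg[s, , drop = FALSE]
    lab[queue] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        nbm <- matrix(nb, 1)
        if (mask[nbm] && lab[nbm] == 0L) {
          lab[nbm] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# Identical partitions up to label renaming.
same_partition <- function(lab1, lab2) {
  f1 <- as.integer(lab1[lab1 != 0 | lab2 != 0])
  f2 <- as.integer(lab2[lab1 != 0 | lab2 != 0])
  if (any(xor(f1 == 0, f2 == 0))) return(FALSE)
  length(unique(f1)) == length(unique(f2)) &&
    length(unique(paste(f1, f2))) == length(unique(f1))
}

# All-pairs maximum distance, double loop.
oracle_max_pairwise <- function(pts) {
  best <- 0
  n <- nrow(pts)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# Per-point nearest neighbour by double loop.
oracle_nnd <- function(pts) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    min(vapply(setdiff(seq_len(n), i), function(j)
      sqrt(sum((pts[i, ] - pts[j, ])^2)), 0))
  }, 0)
}

# Integrated density by explicit per-pixel accumulation with a ray-casting
# point-in-polygon test (independent of mgcv::in.out).
oracle_integrated_density <- function(x, poly) {
  proj <- if (length(dim(x)) == 3L) apply(x, c(1, 2), sum) else x
  acc <- 0
  for (i in seq_len(nrow(proj))) for (j in seq_len(ncol(proj))) {
    if (ray_cast_inside(i - 0.5, j - 0.5, poly)) acc <- acc + proj[i, j]
  }
  acc
}

ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  jj <- n
  for (ii in seq_len(n)) {
    xi <- poly[ii, 1]; yi <- poly[ii, 2]
    xj <- poly[jj, 1]; yj <- poly[jj, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    jj <- ii
  }
  inside
}

# Sholl counts by dense circle sampling (0.005-pixel arc steps), the
# independent route against the package's exact angular-interval counting:
# foreground runs narrower than the step cannot be resolved, so the step
# is kept well below one pixel.
oracle_sholl_counts <- function(mask, center, radii_px, step = 0.005) {
  vapply(radii_px, function(r) {
    if (r <= 0) return(0L)
    n <- max(16L, ceiling(2 * pi * r / step))
    th <- 2 * pi * (seq_len(n) - 1) / n
    px <- round(center[1] + r * cos(th))
    py <- round(center[2] + r * sin(th))
    ok <- px >= 1 & px <= nrow(mask) & py >= 1 & py <= ncol(mask)
    fg <- logical(n)
    fg[ok] <- mask[cbind(px[ok], py[ok])]
    if (!any(fg)) return(0L)
    if (all(fg)) return(1L)
    sum(fg & !c(fg[n], fg[-n]))
  }, 0L)
}

# Regular n-gon approximating a circle of radius r.
regular_polygon <- function(n, r = 50, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Small random binary volume with blob-ish foreground.
random_mask3 <- function(dims, p = 0.15, seed = 1) {
  withr::with_seed(seed, array(runif(prod(dims)) < p, dims))
}
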