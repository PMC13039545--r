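# Imaging quantification: thresholding, segmentation, diameters, NND,
# coverage, internalization, colocalization, integrated density.

test_that("moments threshold separates a bimodal histogram and matches the oracle", {
  cts <- rep(0, 256); cts[11] <- 100; cts[201] <- 100
  th <- moments_threshold(cts)
  expect_gt(th, 10)
  expect_lt(th, 200)
  withr::with_seed(42, {
    for (i in 1:10) {
      counts <- rpois(256, 5) + ifelse(runif(256) < 0.05, rpois(256, 200), 0)
      expect_identical(moments_threshold(counts), oracle_moments_threshold(counts))
    }
  })
  expect_error(moments_threshold(c(0, 10, 0)), class = "retquant_degenerate_histogram")
})

test_that("moments threshold is shift-covariant in the gray levels", {
  withr::with_seed(7, {
    for (i in 1:10) {
      counts <- rpois(200, 5) + ifelse(runif(200) < 0.05, rpois(200, 150), 0)
      k <- sample(1:50, 1)
      expect_equal(moments_threshold(counts, (0:199) + k),
                   moments_threshold(counts, 0:199) + k)
    }
  })
})

test_that("binarize is strict-greater and monotone in the threshold", {
  x <- array(c(0, 5, 10, 20), c(2, 2, 1))
  expect_equal(sum(binarize(x, 20)), 0)   # threshold = max -> empty
  expect_equal(sum(binarize(x, -1)), 4)   # below min -> full
  withr::with_seed(3, {
    v <- array(runif(16^3, 0, 100), c(16, 16, 16))
    ths <- sort(runif(8, 0, 100))
    counts <- vapply(ths, function(t) sum(binarize(v, t)), 0)
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("connected components match flood fill and handle corner contact", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  cs <- connected_components(cube, 26)
  expect_length(cs$clusters, 1)
  expect_equal(nrow(cs$clusters[[1]]), 27)
  # two voxels sharing only a corner
  corner <- array(FALSE, c(4, 4, 4))
  corner[2, 2, 2] <- TRUE; corner[3, 3, 3] <- TRUE
  expect_length(connected_components(corner, 26)$clusters, 1)
  expect_length(connected_components(corner, 6)$clusters, 2)
  expect_length(connected_components(corner, 18)$clusters, 2)
  for (seed in 1:5) {
    m <- random_mask3(c(9, 9, 9), p = 0.2, seed = seed)
    for (conn in c(6, 18, 26)) {
      lab <- connected_components(m, conn)$labels
      expect_true(same_partition(lab, oracle_flood_fill(m, conn)),
                  info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("major diameter equals all-pairs maximum plus one mean pitch", {
  sp <- c(0.25, 0.25, 0.7)
  expect_equal(major_diameter(matrix(c(3, 3, 3), 1), sp), mean(sp))  # 0.4
  # five collinear voxels along x at 0.25 pitch
  vox <- cbind(1:5, 2, 2)
  expect_equal(major_diameter(vox, sp), 4 * 0.25 + mean(sp))  # 1.4
  withr::with_seed(10, {
    for (i in 1:8) {
      n <- sample(5:60, 1)
      v <- unique(cbind(sample(1:12, n, TRUE), sample(1:12, n, TRUE),
                        sample(1:6, n, TRUE)))
      spc <- runif(3, 0.1, 0.8)
      expect_equal(major_diameter(v, spc),
                   oracle_max_pairwise(voxel_centers_um(v, spc)) + mean(spc))
    }
  })
})

test_that("diameter histogram bins, normalizes and reports the sub-cutoff fraction", {
  h <- diameter_histogram(c(0.8, 0.9, 1.6))
  expect_equal(h$frequency[h$breaks[-length(h$breaks)] == 0.75], 2 / 3)
  expect_equal(h$frequency[h$breaks[-length(h$breaks)] == 1.5], 1 / 3)
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$fraction_below_cutoff, 1)
  h0 <- diameter_histogram(numeric(0))
  expect_equal(h0$n_total, 0L)
  withr::with_seed(4, {
    d <- rlnorm(300, log(0.85) + 0.2^2, 0.2)
    hh <- diameter_histogram(d)
    expect_equal(sum(hh$frequency), 1)
    expect_equal(hh$modal_bin, c(0.75, 1.0))
  })
})

test_that("nearest-neighbor distances match brute force", {
  two <- rbind(c(0, 0), c(3, 0))
  nn <- nearest_neighbor_distances(two)
  expect_equal(nn$nnd, c(3, 3))
  expect_equal(nn$mean, 3)
  expect_error(nearest_neighbor_distances(matrix(0, 1, 2)),
               class = "retquant_insufficient_points")
  withr::with_seed(6, {
    for (i in 1:5) {
      P <- matrix(runif(3 * sample(10:80, 1)), ncol = 3)
      expect_equal(nearest_neighbor_distances(P)$nnd, oracle_nnd(P))
    }
  })
})

test_that("coverage: convex-hull cases and monotone growth under added points", {
  roi <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  corners <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(coverage_fraction(corners, roi, shrink = 0)$percent, 100)
  # foreground confined to the left half
  m <- matrix(FALSE, 100, 100)
  withr::with_seed(2, m[cbind(sample(1:100, 400, TRUE), sample(1:50, 400, TRUE))] <- TRUE)
  m[1, 1] <- m[100, 1] <- m[1, 50] <- m[100, 50] <- TRUE
  expect_equal(coverage_fraction(m, shrink = 0)$percent, 50, tolerance = 0.03)
  # empty projection
  expect_equal(coverage_fraction(matrix(FALSE, 10, 10))$percent, 0)
  # adding points never shrinks the convex hull
  withr::with_seed(8, {
    pts <- matrix(runif(40, 10, 90), ncol = 2)
    a1 <- coverage_fraction(pts, roi, shrink = 0)$percent
    more <- rbind(pts, matrix(runif(20, 0, 100), ncol = 2))
    a2 <- coverage_fraction(more, roi, shrink = 0)$percent
    expect_gte(a2, a1)
  })
})

test_that("concave hull encloses all points and tightens onto concave shapes", {
  withr::with_seed(3, {
    p <- cbind(runif(2000, 0, 100), runif(2000, 0, 100))
    p <- p[!(p[, 1] > 50 & p[, 2] > 50), ]
    roi <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
    convex <- coverage_fraction(p, roi, shrink = 0)
    concave <- coverage_fraction(p, roi, shrink = 0.5)
    expect_lt(concave$percent, convex$percent)
    expect_equal(concave$percent, 75, tolerance = 0.08)
    inside <- points_in_polygon(p, concave$boundary)
    on_hull <- apply(p, 1, function(q)
      any(abs(concave$boundary[, 1] - q[1]) < 1e-9 &
            abs(concave$boundary[, 2] - q[2]) < 1e-9))
    expect_true(all(inside | on_hull))
  })
})

test_that("internalization is centroid-based and partition-exact", {
  m <- array(FALSE, c(6, 6, 6)); m[1:6, 1:6, 1:3] <- TRUE
  cs <- list(clusters = lapply(1:10, function(i) {
    z <- if (i <= 3) 2L else 5L
    matrix(c(i %% 6 + 1L, (i * 2L) %% 6 + 1L, z), 1)
  }), labels = array(0L, c(6, 6, 6)))
  class(cs) <- "cluster_set"
  r <- internalization_fraction(cs, m)
  expect_equal(r$percent, 30)
  expect_equal(internalization_fraction(cs, array(FALSE, c(6, 6, 6)))$percent, 0)
  empty <- structure(list(clusters = list(), labels = array(0L, c(6, 6, 6))),
                     class = "cluster_set")
  expect_error(internalization_fraction(empty, m),
               class = "retquant_undefined_fraction")
})

test_that("Manders coefficients: identity, disjoint, arithmetic, intensity mode", {
  a <- array(FALSE, c(20, 20, 1)); a[1:10, 1:10, 1] <- TRUE  # 100 voxels
  b <- array(FALSE, c(20, 20, 1)); b[6:15, 1:20, 1] <- TRUE  # 200 voxels
  r <- manders_coefficients(a, b)           # overlap 5x10 = 50
  expect_equal(r$M1, 0.5); expect_equal(r$M2, 0.25)
  expect_equal(unlist(manders_coefficients(a, a)[c("M1", "M2")]),
               c(M1 = 1, M2 = 1))
  d <- array(FALSE, c(20, 20, 1)); d[16:20, 16:20, 1] <- TRUE
  expect_equal(unlist(manders_coefficients(a, d)[c("M1", "M2")]),
               c(M1 = 0, M2 = 0))
  r2 <- manders_coefficients(a, array(FALSE, c(20, 20, 1)))
  expect_true(is.na(r2$M2)); expect_identical(r2$undefined, "M2")
  ia <- array(2, c(20, 20, 1)); ib <- array(3, c(20, 20, 1))
  ri <- manders_coefficients(a, b, mode = "intensity",
                             intensitiesA = ia, intensitiesB = ib)
  expect_equal(ri$M1, 0.5); expect_equal(ri$M2, 0.25)
})

test_that("integrated density: analytic cases and per-pixel oracle", {
  roi <- cbind(c(0.1, 10, 10, 0.1), c(0.1, 0.1, 10, 10))
  one <- array(3, c(20, 20, 1))
  r1 <- integrated_density(one, list(roi))
  # pixels with centres inside (0.1,10)^2: 10x10 = 100 of intensity 3
  expect_equal(r1$mean, 300)
  two <- array(3, c(20, 20, 2))
  expect_equal(integrated_density(two, list(roi))$mean, 600)
  expect_error(integrated_density(one, list(roi * 10)), "outside")
  withr::with_seed(5, {
    # vertices off the half-integer grid so no pixel centre lies exactly on
    # an edge (there the inside test is implementation-defined)
    x <- array(runif(12 * 12 * 3), c(12, 12, 3))
    poly <- cbind(c(1.2, 11.3, 7.1, 2.2), c(1.1, 2.2, 11.3, 8.2))
    expect_equal(integrated_density(x, list(poly))$mean,
                 oracle_integrated_density(x, poly))
  })
})

test_that("tiff round trip preserves intensities and spacing", {
  withr::with_seed(1, {
    st <- image_stack(list(np = array(runif(8 * 8 * 3, 0, 120), c(8, 8, 3))),
                      c(0.1, 0.1, 0.3))
  })
  base <- file.path(withr::local_tempdir(), "stk")
  write_stack(st, base)
  st2 <- read_stack(base)
  expect_equal(st2$spacing, st$spacing)
  expect_equal(st2$channels$np, st$channels$np, tolerance = 1e-6)
})

test_that("ROI polygons round-trip through JSON", {
  rois <- list(cbind(c(1.5, 9, 8), c(1, 2, 9)), cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
  f <- file.path(withr::local_tempdir(), "rois.json")
  write_rois(rois, f)
  back <- read_rois(f)
  expect_equal(back, rois)
  x <- array(2, c(12, 12, 1))
  expect_equal(integrated_density(x, back)$per_roi,
               integrated_density(x, rois)$per_roi)
})
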