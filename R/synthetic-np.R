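#' Specification of a synthetic nanoparticle stack
#'
#' Bundles the parameters of the confocal-like volume that
#' [generate_np_stack()] renders: clustered sub-micron fluorescent puncta
#' confined to a thin subretinal band over a phagocytic epithelium band,
#' blurred by a Gaussian point-spread function and corrupted by detector
#' noise. Cluster diameters are log-normal; `diameter_mode` is the mode of
#' that distribution (the log-mean is `log(mode) + sigma^2`), emulating
#' particle aggregates whose size histogram peaks just below 1 um.
#'
#' @param shape_xyz integer length-3, stack size in voxels (x, y, z)
#' @param spacing_xyz numeric length-3, um per voxel
#' @param n_clusters number of fluorescent clusters to place
#' @param diameter_mode modal cluster diameter (um)
#' @param diameter_sigma log-scale SD of the diameter distribution
#' @param layer_band_z half-open voxel interval `[lo, hi)` (0-based) of the
#'   outer-retina band holding non-internalized clusters
#' @param rpe_band_z half-open voxel interval of the epithelial band holding
#'   internalized clusters; must not overlap `layer_band_z`
#' @param internalized_fraction fraction of clusters whose centres fall in
#'   the epithelial band; the realized count is `round(fraction * n)`
#' @param psf_sigma Gaussian blur SD (um, isotropic); 0 disables blurring
#' @param amplitude peak intensity of a rendered cluster (arbitrary units)
#' @param noise_gaussian_sd additive (read) noise SD, a.u.; applied after
#'   the photon noise
#' @param noise_poisson_scale photon-counting (shot) noise: counts per
#'   intensity unit (default 1, the dominant noise source of confocal
#'   detection; 0 disables)
#' @param seed integer seed; all randomness in the generator derives from it
#' @return a `stack_spec` list
#' @export
stack_spec <- function(shape_xyz = c(384L, 384L, 48L),
                       spacing_xyz = c(0.05, 0.05, 0.10),
                       n_clusters = 100L,
                       diameter_mode = 0.85,
                       diameter_sigma = 0.2,
                       layer_band_z = c(15L, 48L),
                       rpe_band_z = c(0L, 15L),
                       internalized_fraction = 0.3,
                       psf_sigma = 0.05,
                       amplitude = 100,
                       noise_gaussian_sd = 2,
                       noise_poisson_scale = 1,
                       seed = 1L) {
  spec <- list(shape_xyz = as.integer(shape_xyz), spacing_xyz = as.numeric(spacing_xyz),
               n_clusters = as.integer(n_clusters), diameter_mode = diameter_mode,
               diameter_sigma = diameter_sigma, layer_band_z = as.integer(layer_band_z),
               rpe_band_z = as.integer(rpe_band_z),
               internalized_fraction = internalized_fraction, psf_sigma = psf_sigma,
               amplitude = amplitude, noise_gaussian_sd = noise_gaussian_sd,
               noise_poisson_scale = noise_poisson_scale, seed = as.integer(seed))
  validate_stack_spec(spec)
  class(spec) <- "stack_spec"
  spec
}

validate_stack_spec <- function(s) {
  stopifnot(length(s$shape_xyz) == 3L, all(s$shape_xyz >= 1L),
            length(s$spacing_xyz) == 3L, all(s$spacing_xyz > 0),
            s$n_clusters >= 0L, s$diameter_mode > 0, s$diameter_sigma >= 0,
            s$psf_sigma >= 0, s$amplitude > 0,
            s$noise_gaussian_sd >= 0, s$noise_poisson_scale >= 0)
  if (s$internalized_fraction < 0 || s$internalized_fraction > 1)
    stop("internalized_fraction must be in [0, 1]")
  for (band in list(s$layer_band_z, s$rpe_band_z)) {
    if (length(band) != 2L || band[1] < 0L || band[2] > s$shape_xyz[3] || band[1] >= band[2])
      stop("z bands must be half-open intervals within the stack")
  }
  if (max(s$layer_band_z[1], s$rpe_band_z[1]) < min(s$layer_band_z[2], s$rpe_band_z[2]))
    stop("layer_band_z and rpe_band_z must not overlap")
  invisible(s)
}

#' Render a synthetic nanoparticle stack with ground truth
#'
#' Clusters are solid spheres of the drawn diameter rasterized by
#' centre-sampling (a voxel belongs to a sphere if its centre lies within
#' the radius), placed at mutually non-overlapping centres (separation at
#' least the sum of radii plus one mean voxel pitch, so rasterized spheres
#' can never touch even diagonally), then blurred by the PSF, then
#' corrupted by noise. `round(internalized_fraction * n_clusters)` centres
#' fall in the epithelial z-band, the remainder in the outer-retina band.
#'
#' @param spec a [stack_spec]
#' @return list with `stack` (an [image_stack], channel `"np"`), `masks`
#'   (logical arrays `rpe` and `retina` marking the two z-bands) and
#'   `truth` (data frame: `id`, centre in um, `diameter_um`, `compartment`)
#' @export
generate_np_stack <- function(spec) {
  validate_stack_spec(spec)
  withr::with_seed(spec$seed, generate_np_stack_impl(spec))
}

generate_np_stack_impl <- function(spec) {
  dims <- spec$shape_xyz
  sp <- spec$spacing_xyz
  n <- spec$n_clusters
  n_in <- as.integer(round(spec$internalized_fraction * n))

  diam <- if (n > 0)
    rlnorm(n, meanlog = log(spec$diameter_mode) + spec$diameter_sigma^2,
           sdlog = spec$diameter_sigma)
  else numeric(0)
  compartment <- rep(c("RPE", "retina"), c(n_in, n - n_in))

  # one voxel diagonal on top of the radius sums: rasterized spheres of
  # centre-sampled voxels can then never touch, even at 26-connectivity
  margin <- sqrt(sum(sp^2))
  centers <- place_centers(
    n = n, radii = diam / 2,
    band_of = ifelse(compartment == "RPE", 1L, 2L),
    bands_um = rbind(spec$rpe_band_z * sp[3], spec$layer_band_z * sp[3]),
    field_um = dims[1:2] * sp[1:2], margin = margin)

  vol <- array(0, dims)
  if (n > 0) {
    for (i in seq_len(n)) {
      vol <- render_sphere(vol, centers[i, ], diam[i] / 2, sp, spec$amplitude)
    }
  }
  if (spec$psf_sigma > 0) vol <- gauss_blur3(vol, spec$psf_sigma / sp)
  if (spec$noise_poisson_scale > 0)
    vol[] <- rpois(length(vol), pmax(vol, 0) * spec$noise_poisson_scale) /
      spec$noise_poisson_scale
  if (spec$noise_gaussian_sd > 0)
    vol <- vol + rnorm(length(vol), sd = spec$noise_gaussian_sd)

  zidx <- seq_len(dims[3]) - 1L  # 0-based plane index
  in_band <- function(b) {
    m <- array(FALSE, dims)
    m[, , zidx >= b[1] & zidx < b[2]] <- TRUE
    m
  }
  truth <- data.frame(id = seq_len(n),
                      cx_um = centers[, 1], cy_um = centers[, 2], cz_um = centers[, 3],
                      diameter_um = diam, compartment = compartment,
                      stringsAsFactors = FALSE)
  list(stack = image_stack(list(np = vol), sp),
       masks = list(rpe = in_band(spec$rpe_band_z), retina = in_band(spec$layer_band_z)),
       truth = truth)
}

# Dart-throwing placement of sphere centres with per-point z bands.
place_centers <- function(n, radii, band_of, bands_um, field_um, margin,
                          max_tries = 2000L) {
  centers <- matrix(NA_real_, n, 3)
  if (n == 0L) return(centers)
  for (i in seq_len(n)) {
    band <- bands_um[band_of[i], ]
    r <- radii[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, r, field_um[1] - r), runif(1, r, field_um[2] - r),
             runif(1, band[1], band[2]))
      if (i == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        d <- sqrt(rowSums(sweep(prev, 2, p)^2))
        ok <- all(d >= radii[seq_len(i - 1L)] + r + margin)
      }
      if (ok) { centers[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed)
      stop_retquant(sprintf(
        "could not place cluster %d of %d without overlap: band too crowded", i, n),
        "retquant_packing_error")
  }
  centers
}

# Add a centre-sampled solid sphere of the given radius (um) to a volume.
render_sphere <- function(vol, center_um, r_um, sp, amplitude) {
  dims <- dim(vol)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, floor((center_um[ax] - r_um) / sp[ax] + 0.5))
    hi <- min(dims[ax], ceiling((center_um[ax] + r_um) / sp[ax] + 0.5))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) return(vol)
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  cen <- voxel_centers_um(as.matrix(g), sp)
  inside <- rowSums(sweep(cen, 2, center_um)^2) <= r_um^2
  if (!any(inside)) {
    # guarantee at least the voxel containing the centre
    vi <- pmin(pmax(1L, as.integer(floor(center_um / sp) + 1L)), dims)
    vol[matrix(vi, 1)] <- vol[matrix(vi, 1)] + amplitude
    return(vol)
  }
  idx <- as.matrix(g[inside, , drop = FALSE])
  vol[idx] <- vol[idx] + amplitude
  vol
}
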