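#' Image stacks
#'
#' An `image_stack` holds one or more fluorescence channels as 3D voxel
#' arrays indexed `[x, y, z]`, together with the physical voxel spacing in
#' micrometres. Voxel indices are 1-based in R; the physical coordinate of
#' the centre of voxel `i` along an axis is `(i - 0.5) * spacing`.
#'
#' @param channels named list of numeric 3D arrays (2D arrays are promoted
#'   to a single-plane 3D array), all with identical dimensions
#' @param spacing numeric length-3, micrometres per voxel along x, y, z
#' @return an object of class `image_stack`
#' @export
image_stack <- function(channels, spacing) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of arrays")
  channels <- lapply(channels, function(a) {
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    if (length(dim(a)) != 3L) stop("channel arrays must be 2D or 3D")
    a
  })
  dims <- dim(channels[[1]])
  for (a in channels) if (!identical(dim(a), dims)) stop("channel dimensions differ")
  if (prod(dims) == 0L) stop("empty stack")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (um/voxel)")
  structure(list(channels = channels, spacing = spacing, dim = dims),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d x %d voxels, spacing %s um, channels: %s\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 3), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Physical coordinates (um) of voxel centres given 1-based indices (n x 3).
voxel_centers_um <- function(idx, spacing) {
  sweep(idx - 0.5, 2, spacing, `*`)
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Each channel is written as `<base>_<channel>.tif` (one page per z-plane,
#' 32-bit float, intensities mapped into `[0, 1]` by the recorded `offset`
#' and `scale`), and `<base>.json` records the voxel spacing, channel
#' names and the affine intensity mapping so that `read_stack()`
#' round-trips intensities (including negative detector-noise values)
#' exactly up to float precision.
#'
#' @param stack an [image_stack]
#' @param base path prefix (without extension)
#' @return `base`, invisibly
#' @export
write_stack <- function(stack, base) {
  stopifnot(inherits(stack, "image_stack"))
  offsets <- vapply(stack$channels, function(a) min(0, min(a)), 0)
  scales <- vapply(names(stack$channels), function(ch)
    max(1, max(stack$channels[[ch]]) - offsets[[ch]]), 0)
  for (ch in names(stack$channels)) {
    a <- (stack$channels[[ch]] - offsets[[ch]]) / scales[[ch]]
    pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]))  # rows = y
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", base, ch), bits.per.sample = 32L)
  }
  meta <- list(spacing_um = stack$spacing, channels = as.list(names(stack$channels)),
               scale = as.list(unname(scales)), offset = as.list(unname(offsets)))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_stack
#' @export
read_stack <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  channels <- list()
  for (i in seq_along(meta$channels)) {
    ch <- meta$channels[[i]]
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", base, ch), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    a <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
    off <- if (!is.null(meta$offset)) meta$offset[[i]] else 0
    channels[[ch]] <- a * meta$scale[[i]] + off
  }
  image_stack(channels, meta$spacing_um)
}

#' Read / write regions of interest as JSON polygon lists
#'
#' ROIs are stored as a JSON array of polygons, each an array of `[x, y]`
#' pixel-coordinate pairs, the exchange format consumed by
#' [integrated_density()] and [coverage_fraction()].
#'
#' @param path JSON file path
#' @param rois list of n x 2 polygon vertex matrices
#' @return `read_rois`: a list of polygon matrices
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p)
    do.call(rbind, lapply(p, function(q) as.numeric(unlist(q)))))
}

#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unname), path, digits = NA)
  invisible(path)
}
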