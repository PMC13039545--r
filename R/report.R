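#' Write a reproducible run manifest
#'
#' Records everything needed to re-run a pipeline stage byte-identically:
#' the stage name, every materialized parameter value, MD5 checksums of
#' the input files, the package version and the seed. Written as JSON next
#' to the stage outputs.
#'
#' @param stage stage name (e.g. `"simulate"`, `"particles"`)
#' @param params named list of all stage parameters (defaults included)
#' @param inputs character vector of input file paths (checksummed)
#' @param seed the run seed
#' @param out_dir output directory (created if needed)
#' @return the manifest list, invisibly; written to
#'   `<out_dir>/<stage>_manifest.json`
#' @export
run_manifest <- function(stage, params, inputs = character(0), seed = NA,
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("retquant")),
    seed = seed,
    params = params,
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), basename(inputs)))
    else list())
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Group summary table of per-subject metrics
#'
#' Aggregates a per-subject metric into the figure-panel style summary:
#' group mean, standard error of the mean, n, and the individual values.
#' No inferential statistics are computed.
#'
#' @param df data frame of per-subject results
#' @param value name of the metric column
#' @param group name of the grouping column
#' @return data frame with `group`, `mean`, `sem` (`NA` for n = 1), `n`
#'   and `values` (semicolon-collapsed individual values)
#' @export
summarize_groups <- function(df, value, group) {
  stopifnot(value %in% names(df), group %in% names(df))
  sp <- split(df[[value]], df[[group]])
  out <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    data.frame(group = g, mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v),
               values = paste(format(v, trim = TRUE), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
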