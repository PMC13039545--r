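#!/usr/bin/env Rscript
# Stage 6: aggregate the per-stage outputs into figure-style group tables
# (mean, sem, n, individual values); no inferential statistics.

suppressPackageStartupMessages(library(retquant))
out <- "results/report"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Cluster diameters grouped by compartment of the segmented stack
clusters <- read.csv("results/particles/clusters.csv")
spec <- jsonlite::read_json("results/simulated/np_spec.json",
                            simplifyVector = TRUE)
rpe_hi_um <- spec$rpe_band_z[2] * spec$spacing_xyz[3]
clusters$compartment <- ifelse(clusters$cz_um < rpe_hi_um, "RPE", "retina")
diam_tab <- summarize_groups(clusters, "diameter_um", "compartment")
write.csv(diam_tab, file.path(out, "diameter_by_compartment.csv"),
          row.names = FALSE)

## Microglial shape by state
sholl <- read.csv("results/morphometry/sholl_summary.csv")
circ <- read.csv("results/morphometry/ameboid_circularity.csv")
shape <- rbind(data.frame(state = "ramified", value = sholl$span_px,
                          metric = "branching_span_px"),
               data.frame(state = "ameboid", value = circ$circularity,
                          metric = "circularity"))
write.csv(do.call(rbind, lapply(split(shape, shape$metric), function(d)
  cbind(metric = d$metric[1], summarize_groups(d, "value", "state")))),
  file.path(out, "microglia_shape.csv"), row.names = FALSE)

## Epithelial mosaic summary (interior cells)
rpe <- read.csv("results/morphometry/rpe_cells.csv")
rpe_int <- rpe[!rpe$is_border, ]
rpe_int$group <- "interior"
mosaic <- do.call(rbind, lapply(c("neighbors", "circularity", "area_um2"),
  function(m) cbind(metric = m, summarize_groups(rpe_int, m, "group"))))
write.csv(mosaic, file.path(out, "rpe_mosaic_summary.csv"), row.names = FALSE)

## Unit Z-scores
zt <- read.csv("results/ephys/unit_zscores.csv")
zt$group <- "responding_units"
write.csv(summarize_groups(zt, "max_z", "group"),
          file.path(out, "unit_zscore_summary.csv"), row.names = FALSE)

cat("report tables written to", out, "\n")
for (f in list.files(out)) cat(" -", f, "\n")
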