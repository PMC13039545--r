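#!/usr/bin/env Rscript
# Stage 2: nanoparticle distribution metrics. Reads the simulated stack
# back from disk, segments clusters with the moments auto-threshold,
# and computes the diameter distribution (250-nm bins), nearest-neighbor
# distances, subretinal coverage and the fraction internalized by the
# epithelial band; compares each against the simulation ground truth.

suppressPackageStartupMessages(library(retquant))
sim <- "results/simulated"
out <- "results/particles"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

stack <- read_stack(file.path(sim, "np_stack"))
truth <- read.csv(file.path(sim, "np_truth.csv"))
spec <- jsonlite::read_json(file.path(sim, "np_spec.json"), simplifyVector = TRUE)

cs <- segment_particles(stack)
write.csv(cs$table, file.path(out, "clusters.csv"), row.names = FALSE)
cat(sprintf("segmented %d clusters (truth %d), threshold %.2f\n",
            length(cs$clusters), nrow(truth), cs$threshold))

h <- diameter_histogram(cs$table$diameter_um)
write.csv(data.frame(bin_lo_um = h$breaks[-length(h$breaks)],
                     bin_hi_um = h$breaks[-1],
                     frequency = h$frequency),
          file.path(out, "diameter_histogram.csv"), row.names = FALSE)
cat(sprintf("modal bin [%.2f, %.2f) um; %.1f%% of clusters below 2 um\n",
            h$modal_bin[1], h$modal_bin[2], 100 * h$fraction_below_cutoff))

nn <- nearest_neighbor_distances(as.matrix(cs$table[, c("cx_um", "cy_um", "cz_um")]))
cat(sprintf("mean NND %.2f um\n", nn$mean))

proj <- apply(binarize(stack$channels$np, cs$threshold), c(1, 2), any)
cov <- coverage_fraction(proj, shrink = 0.5)
cat(sprintf("coverage of the field: %.1f%% (concave boundary, shrink 0.5)\n",
            cov$percent))

rpe_mask <- array(FALSE, dim(stack$channels$np))
rpe_mask[, , seq_len(dim(rpe_mask)[3]) - 1 < spec$rpe_band_z[2]] <- TRUE
intr <- internalization_fraction(cs, rpe_mask)
cat(sprintf("internalized by the epithelial band: %.1f%% (truth %.1f%%)\n",
            intr$percent, 100 * mean(truth$compartment == "RPE")))

write.csv(data.frame(metric = c("n_clusters", "n_clusters_truth", "mean_nnd_um",
                                "coverage_pct", "internalized_pct",
                                "internalized_pct_truth", "frac_below_2um"),
                     value = c(length(cs$clusters), nrow(truth), nn$mean,
                               cov$percent, intr$percent,
                               100 * mean(truth$compartment == "RPE"),
                               h$fraction_below_cutoff)),
          file.path(out, "summary.csv"), row.names = FALSE)

run_manifest("particles",
             params = list(connectivity = cs$connectivity,
                           threshold = cs$threshold, shrink = 0.5),
             inputs = file.path(sim, c("np_truth.csv", "np_spec.json")),
             seed = NA, out_dir = out)
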