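#!/usr/bin/env Rscript
# Stage 1: simulate every input class of the study with known ground truth.
# Writes the confocal-like nanoparticle stack (TIFF + JSON sidecar), the
# microglia and epithelial-mosaic images, the evoked-potential and spiking
# recordings, and the behavior traces under results/simulated/.

suppressPackageStartupMessages(library(retquant))
seed <- 20260924L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Nanoparticle stack at study conditions (100 clusters, 30% internalized)
spec <- stack_spec(seed = seed)
np <- generate_np_stack(spec)
write_stack(np$stack, file.path(out, "np_stack"))
write.csv(np$truth, file.path(out, "np_truth.csv"), row.names = FALSE)
writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA),
           file.path(out, "np_spec.json"))
cat(sprintf("stack: %d clusters, %.0f%% internalized by construction\n",
            nrow(np$truth), 100 * mean(np$truth$compartment == "RPE")))

## Microglia: one ramified and one ameboid cohort
ram <- generate_microglia(3, "ramified", field_px = 420, soma_radius_px = 6,
                          branch_length_px = 45, seed = seed)
amo <- generate_microglia(3, "ameboid", field_px = 420, soma_radius_px = 8,
                          blob_irregularity = 0.15, seed = seed + 1L)
invisible(tiff::writeTIFF(t(ram$mask * 1), file.path(out, "microglia_ramified.tif")))
invisible(tiff::writeTIFF(t(amo$mask * 1), file.path(out, "microglia_ameboid.tif")))
write.csv(rbind(ram$truth, amo$truth), file.path(out, "microglia_truth.csv"),
          row.names = FALSE)

## Epithelial mosaic
mo <- generate_rpe_mosaic(150, jitter = 0.12, field_px = 300, seed = seed)
invisible(tiff::writeTIFF(t(mo$labels / max(mo$labels)),
                          file.path(out, "rpe_labels.tif"),
                          bits.per.sample = 16L))
write.csv(mo$truth, file.path(out, "rpe_truth.csv"), row.names = FALSE)
cat(sprintf("mosaic: %d cells, %d interior\n", nrow(mo$truth),
            sum(!mo$truth$is_border)))

## Flash VEP (200 sweeps) and pattern series
fvep <- generate_vep_recording(n_trials = 200, evoked_amplitude = 50,
                               latency_ms = 100, noise_sd = 20, seed = seed)
utils::write.csv(cbind(t_s = fvep$t_s, as.data.frame(fvep$trials)),
                 file.path(out, "fvep_trials.csv"), row.names = FALSE)
write.csv(fvep$amplitude_table, file.path(out, "pvep_amplitudes.csv"),
          row.names = FALSE)
write.csv(fvep$truth, file.path(out, "vep_truth.csv"), row.names = FALSE)

## Spiking (50 trials, gain 3 in the 150-500 ms window)
spk <- generate_spike_trains(n_units = 12, baseline_rate_hz = 10, gain = 3,
                             n_trials = 50, seed = seed)
write.csv(spk$spikes, file.path(out, "spikes.csv"), row.names = FALSE)
write.csv(spk$truth, file.path(out, "spikes_truth.csv"), row.names = FALSE)

## Behavior: OMR repeats over frequencies, plus a conditioning session
freqs <- c(0.05, 0.1, 0.2, 0.3, 0.4)
omr <- do.call(rbind, lapply(seq_along(freqs), function(i) {
  do.call(rbind, lapply(1:4, function(rep) {
    conc <- max(0, 40 * (1 - freqs[i]) - 8 * (rep %% 2))
    tr <- generate_behavior_trace(concordant_s = round(conc, 1),
                                  discordant_s = 30, neither_s = 5,
                                  condition = freqs[i],
                                  seed = seed + 10L * i + rep)
    tr$repeat_id <- rep
    tr
  }))
}))
write.csv(omr, file.path(out, "omr_traces.csv"), row.names = FALSE)

cond_frac <- c(seq(0.05, 0.65, by = 0.1), 0.2, 0.5, 0.3)
cond_len <- c(rep(30, 7), 120, 180, 300)
cond_phase <- c(paste0("pairing_", 1:7), "cue_dark", "cue_cs", "context")
cond <- do.call(rbind, lapply(seq_along(cond_phase), function(i) {
  tr <- generate_behavior_trace(freezing_fraction = cond_frac[i],
                                session_s = cond_len[i],
                                condition = cond_phase[i], seed = seed + 100L + i)
  tr
}))
write.csv(cond, file.path(out, "conditioning_traces.csv"), row.names = FALSE)

run_manifest("simulate", params = unclass(spec), seed = seed, out_dir = out)
cat("simulation written to", out, "\n")
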