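#!/usr/bin/env Rscript
# Stage 4: visual-function electrophysiology. Flash VEP detection on the
# 200-sweep average, visual acuity from the pattern-series amplitude
# decay, the peristimulus spectral Z-map, and single-unit PSTH / firing
# rate Z-scores with low-rate unit exclusion.

suppressPackageStartupMessages(library(retquant))
sim <- "results/simulated"
out <- "results/ephys"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Flash VEP on the averaged trace
trials <- as.matrix(read.csv(file.path(sim, "fvep_trials.csv")))
t_s <- trials[, 1]
trials <- trials[, -1, drop = FALSE]
truth <- read.csv(file.path(sim, "vep_truth.csv"))
fs <- round(1 / median(diff(t_s)))
onset_s <- -t_s[1]
avg <- average_sweeps(trials, 200)
vep <- detect_vep(avg, fs, onset_s)
cat(sprintf("fVEP: detected=%s amplitude %.1f uV (truth %.0f), latency %.1f ms (truth %.0f)\n",
            vep$detected, vep$amplitude, truth$evoked_amplitude,
            vep$latency_ms, truth$latency_ms))
write.csv(data.frame(detected = vep$detected, amplitude_uv = vep$amplitude,
                     latency_ms = vep$latency_ms, noise_sd = vep$noise_sd,
                     n_sweeps = ncol(trials)),
          file.path(out, "fvep.csv"), row.names = FALSE)

## Visual acuity from the pattern series
amp <- read.csv(file.path(sim, "pvep_amplitudes.csv"))
fit <- estimate_acuity(amp$freq_c_per_deg, amp$amplitude_uv,
                       detected = amp$amplitude_uv > 0)
cat(sprintf("pVEP acuity: %.3f c/deg (truth %.3f), slope %.1f uV/log10, r^2 %.3f\n",
            fit$acuity_c_per_deg, truth$acuity_c_per_deg, fit$slope,
            fit$r_squared))
write.csv(data.frame(acuity_c_per_deg = fit$acuity_c_per_deg,
                     slope = fit$slope, intercept = fit$intercept,
                     r_squared = fit$r_squared, n_points = fit$n_points),
          file.path(out, "acuity.csv"), row.names = FALSE)

## Spectral Z-map of the first low-pass-filtered sweep
x <- lowpass_notch(trials[, 1], fs)
zm <- spectral_zscore(x, fs, onset_s)
zdf <- data.frame(freq_hz = rep(zm$freq_hz, ncol(zm$z)),
                  time_s = rep(zm$time_s, each = nrow(zm$z)),
                  z = as.numeric(zm$z))
write.csv(zdf, file.path(out, "spectral_zmap.csv"), row.names = FALSE)
cat(sprintf("spectral map: %d bands x %d bins, max Z %.1f\n",
            nrow(zm$z), ncol(zm$z), max(zm$z, na.rm = TRUE)))

## Spiking: PSTH and max firing-rate Z per unit
spk <- read.csv(file.path(sim, "spikes.csv"))
spk_truth <- read.csv(file.path(sim, "spikes_truth.csv"))
units <- sort(unique(spk$unit))
mean_rates <- vapply(units, function(u) sum(spk$unit == u) / (50 * 1), 0)
keep <- filter_units(mean_rates)
cat(sprintf("units: %d total, %d retained at the 0.2 Hz criterion\n",
            length(units), sum(keep)))
rows <- lapply(units[keep], function(u) {
  su <- spk[spk$unit == u, ]
  pp <- psth(su$t_s, su$trial, onsets = 0.2, n_trials = 50)
  z <- spiking_zscore(pp$rate_hz, pp$t_s)
  data.frame(unit = u, mean_rate_hz = mean_rates[units == u],
             max_z = z$max_z, t_max_s = z$t_max)
})
ztab <- do.call(rbind, rows)
write.csv(ztab, file.path(out, "unit_zscores.csv"), row.names = FALSE)
cat(sprintf("median max Z %.1f in the 150-500 ms window (rate gain %.0fx)\n",
            median(ztab$max_z), spk_truth$gain[1]))

run_manifest("ephys", params = list(search_ms = c(75, 150), k = 2,
                                    psth_bin_s = 0.01, smooth_s = 0.05,
                                    response_s = c(0.15, 0.5)),
             inputs = file.path(sim, c("fvep_trials.csv", "pvep_amplitudes.csv",
                                       "spikes.csv")),
             seed = NA, out_dir = out)
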