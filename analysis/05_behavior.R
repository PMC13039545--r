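#!/usr/bin/env Rscript
# Stage 5: visual behavior. Optomotor scores per spatial frequency
# (mean over repeats; 1.0 is the perception threshold) and the
# classical-conditioning freezing summary.

suppressPackageStartupMessages(library(retquant))
sim <- "results/simulated"
out <- "results/behavior"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

omr_raw <- read.csv(file.path(sim, "omr_traces.csv"))
traces <- split(omr_raw, interaction(omr_raw$condition, omr_raw$repeat_id,
                                     drop = TRUE))
scores <- omr_scores(traces)
scores$above_threshold <- scores$score >= 1.0
write.csv(scores, file.path(out, "omr_scores.csv"), row.names = FALSE)
cat("OMR scores by spatial frequency:\n")
print(scores, row.names = FALSE)
perceived <- suppressWarnings(max(as.numeric(scores$condition)[scores$above_threshold]))
cat(sprintf("highest perceived frequency: %.2f c/deg\n", perceived))

cond_raw <- read.csv(file.path(sim, "conditioning_traces.csv"))
cond_traces <- split(cond_raw, cond_raw$condition)
summ <- conditioning_summary(cond_traces)
write.csv(summ$pairings, file.path(out, "conditioning_pairings.csv"),
          row.names = FALSE)
write.csv(data.frame(phase = c("cue_dark", "cue_cs", "cs_minus_dark", "context"),
                     freezing_pct = c(summ$cue["dark"], summ$cue["cs"],
                                      summ$cue["cs_minus_dark"], summ$context_pct)),
          file.path(out, "conditioning_summary.csv"), row.names = FALSE)
cat(sprintf("cue recall: dark %.0f%%, CS %.0f%% (difference %.0f points); context %.0f%%\n",
            summ$cue["dark"], summ$cue["cs"], summ$cue["cs_minus_dark"],
            summ$context_pct))

run_manifest("behavior", params = list(aggregation = "mean_over_repeats"),
             inputs = file.path(sim, c("omr_traces.csv", "conditioning_traces.csv")),
             seed = NA, out_dir = out)
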