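# The generators must be deterministic under a fixed seed, enumerate every
# generated object in their ground-truth tables, and honour their exact
# construction rules (internalized counts, state durations, analytic truth).

small_spec <- function(...) {
  do.call(stack_spec, utils::modifyList(
    list(shape_xyz = c(144L, 144L, 16L), spacing_xyz = c(0.05, 0.05, 0.1),
         n_clusters = 10L, layer_band_z = c(5L, 16L), rpe_band_z = c(0L, 5L)),
    list(...)))
}

test_that("nanoparticle stack generator is deterministic and conserves ground truth", {
  g1 <- generate_np_stack(small_spec(seed = 11L))
  g2 <- generate_np_stack(small_spec(seed = 11L))
  expect_identical(g1$stack$channels$np, g2$stack$channels$np)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_np_stack(small_spec(seed = 12L))
  expect_false(identical(g1$stack$channels$np, g3$stack$channels$np))
  expect_equal(nrow(g1$truth), 10L)
  expect_false(any(duplicated(g1$truth$id)))
  # centres inside the stack and inside their stated band
  sp <- small_spec(seed = 11L)
  z_vox <- g1$truth$cz_um / sp$spacing_xyz[3]
  in_rpe <- z_vox >= sp$rpe_band_z[1] & z_vox < sp$rpe_band_z[2]
  expect_identical(in_rpe, g1$truth$compartment == "RPE")
})

test_that("internalized count follows the rounding rule exactly", {
  g <- generate_np_stack(small_spec(internalized_fraction = 0.3, seed = 2L))
  expect_identical(sum(g$truth$compartment == "RPE"), 3L)
  g2 <- generate_np_stack(small_spec(internalized_fraction = 0.25, seed = 2L))
  expect_identical(sum(g2$truth$compartment == "RPE"),
                   as.integer(round(0.25 * 10)))
})

test_that("zero clusters give a pure-noise stack with empty ground truth", {
  g <- generate_np_stack(small_spec(n_clusters = 0L, seed = 5L))
  expect_equal(nrow(g$truth), 0L)
  expect_true(sd(g$stack$channels$np) > 0)  # noise only
})

test_that("infeasible packing raises a packing error", {
  expect_error(
    generate_np_stack(small_spec(n_clusters = 2000L, seed = 1L)),
    class = "retquant_packing_error")
})

test_that("non-overlap: centre separations exceed the sum of radii", {
  g <- generate_np_stack(small_spec(n_clusters = 10L, seed = 21L))
  cen <- as.matrix(g$truth[, c("cx_um", "cy_um", "cz_um")])
  r <- g$truth$diameter_um / 2
  d <- as.matrix(dist(cen))
  need <- outer(r, r, `+`)
  diag(d) <- Inf
  expect_true(all(d >= need))
})

test_that("ameboid ground-truth circularity is 1 for a perfect disk", {
  g <- generate_microglia(2, "ameboid", field_px = 200, soma_radius_px = 8,
                          blob_irregularity = 0, seed = 2L)
  expect_equal(g$truth$circularity, c(1, 1), tolerance = 1e-4)
  gi <- generate_microglia(2, "ameboid", field_px = 200, soma_radius_px = 8,
                           blob_irregularity = 0.2, seed = 2L)
  expect_true(all(gi$truth$circularity < 1))
})

test_that("ramified ground-truth span equals the constructed branch length", {
  g <- generate_microglia(1, "ramified", field_px = 301, soma_radius_px = 6,
                          n_primary = 4, branch_length_px = 60, n_segments = 1,
                          turn_sd = 0, branch_prob = 0,
                          primary_angles = c(0, pi / 2, pi, 3 * pi / 2), seed = 3L)
  expect_equal(g$truth$span_px, 60)
  g2 <- generate_microglia(1, "ramified", field_px = 301, seed = 9L)
  expect_identical(g2$mask,
                   generate_microglia(1, "ramified", field_px = 301, seed = 9L)$mask)
})

test_that("hexagonal mosaic: interior cells have 6 neighbours; density is exact", {
  mo <- generate_rpe_mosaic(64, jitter = 0, field_px = 200, seed = 3L)
  interior <- !mo$truth$is_border
  expect_true(sum(interior) > 10)
  expect_true(all(mo$truth$n_neighbors[interior] == 6))
  expect_equal(mo$density_per_px2, nrow(mo$truth) / 200^2)
  expect_identical(mo$labels,
                   generate_rpe_mosaic(64, jitter = 0, field_px = 200, seed = 3L)$labels)
})

test_that("vep generator: noiseless average peaks at the set amplitude and latency", {
  g <- generate_vep_recording(n_trials = 5, noise_sd = 0, evoked_amplitude = 30,
                              latency_ms = 120, seed = 2L)
  avg <- average_sweeps(g$trials)
  ipk <- which.max(abs(avg))
  expect_equal(max(abs(avg)), 30, tolerance = 1e-9)
  expect_equal(g$t_s[ipk] * 1000, 120, tolerance = 1000 / g$fs)
  # identical trials when noiseless
  expect_equal(g$trials[, 1], g$trials[, 5])
  expect_error(generate_vep_recording(fs = 500), "1 kHz")
})

test_that("vep generator: noiseless amplitude table vanishes exactly at the acuity", {
  g <- generate_vep_recording(freqs = c(0.05, 0.1, 0.2, 0.4), amp_noise_sd = 0,
                              acuity_c_per_deg = 0.4, noise_sd = 0, seed = 1L)
  tab <- g$amplitude_table
  expect_equal(tab$amplitude_uv[tab$freq_c_per_deg == 0.4], 0)
  expect_true(all(diff(tab$amplitude_uv) < 0))
})

test_that("spike generator: gain 1 is homogeneous Poisson with the right mean", {
  s <- generate_spike_trains(n_units = 1, baseline_rate_hz = 10, gain = 1,
                             n_trials = 100, trial_dur_s = 1, seed = 8L)
  n <- nrow(s$spikes)
  expect_gt(n, 1000 - 4 * sqrt(1000))
  expect_lt(n, 1000 + 4 * sqrt(1000))
  s2 <- generate_spike_trains(n_units = 1, baseline_rate_hz = 10, gain = 1,
                              n_trials = 100, trial_dur_s = 1, seed = 8L)
  expect_identical(s$spikes, s2$spikes)
})

test_that("behavior traces reproduce requested durations exactly", {
  tr <- generate_behavior_trace(concordant_s = 30, discordant_s = 30,
                                neither_s = 10, seed = 1L)
  d <- tapply(rep(0.1, nrow(tr)), tr$state, sum)
  expect_equal(as.numeric(d[c("concordant", "discordant", "neither")]),
               c(30, 30, 10))
  trf <- generate_behavior_trace(freezing_fraction = 0.25, session_s = 300, seed = 4L)
  expect_equal(sum(trf$state == "freezing") * 0.1, 75)
  expect_identical(tr, generate_behavior_trace(concordant_s = 30, discordant_s = 30,
                                               neither_s = 10, seed = 1L))
  expect_error(generate_behavior_trace(concordant_s = 100, discordant_s = 100,
                                       session_s = 60, seed = 1L), "exceed")
})
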