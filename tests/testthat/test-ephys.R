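# Evoked potentials, spectra and spiking: filtering, averaging, detection,
# acuity extrapolation, Z-scoring.

test_that("filters: DC removal, notch attenuation, neighbour preservation", {
  fs <- 5000
  t <- seq(0, 1, 1 / fs)
  dc <- bandpass_lfp(rep(5, length(t)), fs)
  expect_lt(mean(abs(dc)), 0.05)  # < 1% of the 5-unit offset
  mid <- 1000:4000  # avoid filtfilt edge transients
  y50 <- lowpass_notch(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(y50[mid])), 0.1)  # >= 90% attenuation at 50 Hz
  y45 <- lowpass_notch(sin(2 * pi * 45 * t), fs)
  expect_equal(max(abs(y45[mid])), 1, tolerance = 0.1)
  expect_error(bandpass_lfp(t, fs = 150, high = 100),
               class = "retquant_nyquist_error")
})

test_that("filters and averaging commute with scalar gain", {
  fs <- 2000
  withr::with_seed(5, x <- rnorm(fs))
  for (f in list(function(z) bandpass_lfp(z, fs),
                 function(z) lowpass_notch(z, fs),
                 function(z) bandpass_spikes(z, 8000, 300, 3000))) {
    expect_equal(f(3.7 * x), 3.7 * f(x), tolerance = 1e-10)
  }
  m <- matrix(x, ncol = 4)
  expect_equal(average_sweeps(3.7 * m), 3.7 * average_sweeps(m), tolerance = 1e-12)
})

test_that("sweep averaging: identity cases and 1/sqrt(n) noise scaling", {
  m <- matrix(rep(sin(1:100), 3), ncol = 3)
  expect_equal(average_sweeps(m), m[, 1])
  expect_equal(average_sweeps(m[, 1, drop = FALSE]), m[, 1])
  g <- generate_vep_recording(n_trials = 200, evoked_amplitude = 0,
                              noise_sd = 20, seed = 3L)
  ratio <- sd(average_sweeps(g$trials)) / mean(apply(g$trials, 2, sd)) * sqrt(200)
  expect_equal(ratio, 1, tolerance = 0.2)
})

test_that("VEP detection: threshold behaviour and latency accuracy", {
  fs <- 5000
  n <- round(0.7 * fs)
  t_ms <- ((seq_len(n) - 1) / fs - 0.2) * 1000
  flat <- rep(0, n)
  r0 <- detect_vep(flat, fs, onset_s = 0.2)
  expect_false(r0$detected)
  withr::with_seed(21, base_noise <- rnorm(n, sd = 2))
  big <- base_noise + 10 * 2 * exp(-(t_ms - 100)^2 / (2 * 8^2))
  r1 <- detect_vep(big, fs, onset_s = 0.2)
  expect_true(r1$detected)
  expect_equal(r1$latency_ms, 100, tolerance = 5)
  # 1.5 x SD deflection with k = 2 stays undetected (noise confined to the
  # baseline so the construction is deterministic)
  base_only <- base_noise * (t_ms < 0)
  bsd <- sd(base_only[t_ms >= -100 & t_ms < 0])
  small <- base_only + 1.5 * bsd * exp(-(t_ms - 100)^2 / (2 * 8^2))
  r2 <- detect_vep(small, fs, onset_s = 0.2)
  expect_false(r2$detected)
  expect_true(is.na(r2$latency_ms))
  # negative-going responses are detected with positive amplitude
  neg <- base_noise - 40 * exp(-(t_ms - 110)^2 / (2 * 8^2))
  r3 <- detect_vep(neg, fs, onset_s = 0.2)
  expect_true(r3$detected)
  expect_gt(r3$amplitude, 30)
  expect_error(detect_vep(flat, fs, 0.2, baseline_ms = c(50, 100)), "precede")
})

test_that("generator-to-detector round trip finds amplitude and latency", {
  g <- generate_vep_recording(n_trials = 200, evoked_amplitude = 50,
                              latency_ms = 100, noise_sd = 20, seed = 2L)
  r <- vep_from_trials(g$trials, g$fs, g$onset_s)
  expect_true(r$detected)
  expect_equal(r$amplitude, 50, tolerance = 0.15)
  expect_equal(r$latency_ms, 100, tolerance = 5)
  expect_equal(r$noise_sd, 20, tolerance = 0.1)  # single-sweep noise level
})

test_that("acuity: exact on constructed lines, robust under noise", {
  f <- c(0.05, 0.1, 0.2, 0.3)
  A <- -20 * (log10(f) - log10(0.4))
  fit <- estimate_acuity(f, A)
  expect_equal(fit$acuity_c_per_deg, 0.4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(estimate_acuity(f, rev(A)), class = "retquant_no_decay")
  expect_error(estimate_acuity(f[1:2], A[1:2]),
               class = "retquant_insufficient_points")
  errs <- vapply(1:50, function(s) {
    g <- generate_vep_recording(freqs = f, acuity_c_per_deg = 0.4, slope = 20,
                                amp_noise_sd = 0.05 * max(A), noise_sd = 0,
                                n_trials = 1, seed = 3000 + s)
    ft <- estimate_acuity(g$amplitude_table$freq_c_per_deg,
                          g$amplitude_table$amplitude_uv)
    abs(ft$acuity_c_per_deg - 0.4) / 0.4
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("spectral Z-map: null is centred, injected band attains the maximum", {
  g <- generate_vep_recording(n_trials = 1, fs = 2000, noise_sd = 10,
                              evoked_amplitude = 0, prestim_s = 0.3,
                              poststim_s = 0.6, seed = 9L)
  x <- g$trials[, 1]
  zm0 <- spectral_zscore(x, 2000, g$onset_s)
  expect_lt(abs(mean(zm0$z[, zm0$time_s > 0], na.rm = TRUE)), 0.5)
  burst <- 20 * sin(2 * pi * 30 * (seq_along(x) - 1) / 2000) *
    (g$t_s > 0.05 & g$t_s < 0.3)
  zm <- spectral_zscore(x + burst, 2000, g$onset_s)
  imax <- which(zm$z == max(zm$z, na.rm = TRUE), arr.ind = TRUE)
  band <- zm$freq_hz[imax[1]]
  expect_lt(abs(band - 30), diff(zm$freq_hz[1:2]) + 1e-9)
  # signal periodic at the bin hop: every spectral bin is identical, so
  # there is no stimulus-locked power change anywhere (zero numerator;
  # the zero-SD baseline rows are flagged as undefined)
  per <- rep(sin(2 * pi * (0:9) / 10), length.out = length(x))  # period = 5 ms hop
  zp <- spectral_zscore(per, 2000, g$onset_s)
  expect_lt(diff(range(apply(zp$power, 1, function(p) diff(range(p))))), 1e-8)
  expect_equal(length(zp$flagged), nrow(zp$power))
  expect_true(all(is.na(zp$z)))
})

test_that("PSTH arithmetic and Poisson mean recovery", {
  p <- psth(rep(0.225, 50), 1:50, onsets = 0.2, n_trials = 50)
  hot <- which(abs(p$t_s - 0.02) < 1e-9)
  expect_equal(p$rate_hz[hot], 100)
  expect_equal(sum(p$rate_hz), 100)  # all other bins zero
  p0 <- psth(numeric(0), integer(0), onsets = 0.2, n_trials = 50)
  expect_true(all(p0$rate_hz == 0))
  s <- generate_spike_trains(n_units = 1, baseline_rate_hz = 10, gain = 1,
                             n_trials = 200, trial_dur_s = 1, seed = 7L)
  pp <- psth(s$spikes$t_s, s$spikes$trial, onsets = 0.2, n_trials = 200)
  expect_equal(mean(pp$rate_hz), 10, tolerance = 0.1)
})

test_that("spiking Z-score rises monotonically with response gain", {
  zs <- vapply(c(1, 2, 4), function(gg) {
    s <- generate_spike_trains(n_units = 1, baseline_rate_hz = 10, gain = gg,
                               n_trials = 50, seed = 4L)
    pp <- psth(s$spikes$t_s, s$spikes$trial, onsets = 0.2, n_trials = 50)
    spiking_zscore(pp$rate_hz, pp$t_s)$max_z
  }, 0)
  expect_true(all(diff(zs) > 0))
  expect_error(spiking_zscore(rep(5, 100), seq(-0.5, 0.49, 0.01)),
               class = "retquant_degenerate_baseline")
})

test_that("unit filtering keeps the 0.2 Hz boundary", {
  expect_identical(filter_units(c(0.1, 0.2, 3)), c(FALSE, TRUE, TRUE))
  expect_identical(sum(filter_units(c(0.05, 0.2, 3))), 2L)
})

test_that("null VEP detection rate at k = 2 stays below 10%", {
  hits <- vapply(1:200, function(s) {
    g <- generate_vep_recording(n_trials = 20, evoked_amplitude = 0,
                                noise_sd = 15, seed = 5000 + s)
    vep_from_trials(g$trials, g$fs, g$onset_s)$detected
  }, TRUE)
  expect_lt(mean(hits), 0.10)
})
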