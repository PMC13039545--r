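#' Zero-phase filters for evoked-potential and spiking signals
#'
#' Butterworth designs applied forward and backward, so the group delay is
#' zero and response latencies are unbiased. The combined
#' forward-backward response `|H|^2` is applied in the frequency domain on
#' a reflection-padded trace: numerically this is exactly linear in the
#' input even at the extreme 0.1 Hz corner, where time-domain IIR
#' recursions lose several digits. `bandpass_lfp` is the 0.1-100 Hz
#' evoked-potential band, `lowpass_notch` the 300 Hz low-pass plus 50 Hz
#' power-line notch used before probe VEP/spectral analysis, and
#' `bandpass_spikes` the 300 Hz-5 kHz band preceding spike detection.
#'
#' @param x numeric vector (one channel)
#' @param fs sampling rate (Hz)
#' @param low,high band edges (Hz)
#' @param lp low-pass cutoff (Hz)
#' @param notch notch centre frequency (Hz)
#' @param notch_halfwidth half-width of the stop band (Hz)
#' @return filtered vector of the same length
#' @export
bandpass_lfp <- function(x, fs, low = 0.1, high = 100) {
  check_cutoffs(fs, low, high)
  b <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  # demean first: the 0.1 Hz corner has a multi-second impulse response, so
  # removing the DC component up front avoids start-up transients on traces
  # shorter than that
  zero_phase_apply(x - mean(x), b)
}

#' @rdname bandpass_lfp
#' @export
lowpass_notch <- function(x, fs, lp = 300, notch = 50, notch_halfwidth = 2) {
  check_cutoffs(fs, lp)
  check_cutoffs(fs, notch + notch_halfwidth)
  blp <- signal::butter(4, lp / (fs / 2), type = "low")
  bn <- signal::butter(2, c(notch - notch_halfwidth, notch + notch_halfwidth) / (fs / 2),
                       type = "stop")
  zero_phase_apply(zero_phase_apply(x, blp), bn)
}

#' @rdname bandpass_lfp
#' @export
bandpass_spikes <- function(x, fs, low = 300, high = 5000) {
  check_cutoffs(fs, low, high)
  b <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  zero_phase_apply(x, b)
}

# Forward-backward (zero-phase) application of a digital filter: multiply
# the spectrum of the reflection-padded trace by |H(e^{jw})|^2.
zero_phase_apply <- function(x, flt) {
  n <- length(x)
  pad <- min(n - 1L, max(64L, n %/% 2))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  w <- 2 * pi * (seq_len(m) - 1L) / m
  klen <- max(length(flt$b), length(flt$a))
  num <- vapply(seq_len(klen) - 1L, function(k) exp(-1i * w * k), complex(m))
  H <- as.vector(num[, seq_along(flt$b), drop = FALSE] %*% flt$b) /
    as.vector(num[, seq_along(flt$a), drop = FALSE] %*% flt$a)
  y <- Re(fft(fft(xp) * Mod(H)^2, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

check_cutoffs <- function(fs, ...) {
  cut <- c(...)
  if (any(cut >= fs / 2))
    stop_retquant(sprintf("cutoff %.3g Hz is at or above Nyquist (%.3g Hz)",
                          max(cut), fs / 2), "retquant_nyquist_error")
  if (any(cut <= 0)) stop("cutoffs must be positive")
  invisible(TRUE)
}

#' Average a trial matrix into a single sweep
#'
#' Pointwise mean across trials (columns), optionally over the first
#' `n_sweeps` only. Trials are assumed onset-aligned, as produced by the
#' recording generators.
#'
#' @param trials samples x trials numeric matrix
#' @param n_sweeps number of sweeps to average (default all)
#' @return numeric vector (one averaged trace)
#' @export
average_sweeps <- function(trials, n_sweeps = NULL) {
  trials <- as.matrix(trials)
  n_sweeps <- n_sweeps %||% ncol(trials)
  stopifnot(n_sweeps >= 1, n_sweeps <= ncol(trials))
  rowMeans(trials[, seq_len(n_sweeps), drop = FALSE])
}

#' Detect a visually evoked potential on an averaged trace
#'
#' Finds the signed extremum of largest absolute deviation from the
#' baseline mean inside the post-stimulus search window (default
#' 75-150 ms). The response is detected iff the peak-to-baseline amplitude
#' exceeds `k` times the baseline standard deviation (default 2). Latency
#' is stimulus onset to peak time. Undetected responses report `NA`
#' amplitude and latency (physiologically, an infinite latency).
#'
#' @param x averaged trace (numeric vector)
#' @param fs sampling rate (Hz)
#' @param onset_s stimulus onset time relative to the first sample (s)
#' @param search_ms post-onset search window, ms (default `c(75, 150)`)
#' @param baseline_ms pre-onset baseline window, ms before onset
#'   (default `c(-100, 0)`); must precede the search window
#' @param k detection threshold in baseline SDs (default 2)
#' @param noise_sd optional externally estimated noise SD (uV) against
#'   which the `k`-fold criterion is applied; by default the SD of the
#'   baseline window of `x` itself. Supplying the single-sweep noise level
#'   (see [vep_from_trials()]) makes the criterion a physiological gate
#'   rather than a test against the strongly autocorrelated residue of
#'   the averaged trace.
#' @return a `vep_result`: list with `detected`, `amplitude`,
#'   `latency_ms`, `noise_sd`, `search_ms`, `k`
#' @export
detect_vep <- function(x, fs, onset_s, search_ms = c(75, 150),
                       baseline_ms = c(-100, 0), k = 2, noise_sd = NULL) {
  stopifnot(diff(search_ms) > 0, diff(baseline_ms) > 0)
  if (baseline_ms[2] > search_ms[1])
    stop("baseline window must precede the search window")
  t_ms <- (seq_along(x) - 1) / fs * 1000 - onset_s * 1000
  base <- x[t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]]
  win <- which(t_ms >= search_ms[1] & t_ms <= search_ms[2])
  if (length(base) < 2 || length(win) == 0)
    stop("baseline or search window contains no samples")
  b0 <- mean(base); bsd <- noise_sd %||% sd(base)
  dev <- x[win] - b0
  ipk <- win[which.max(abs(dev))]
  amp <- abs(x[ipk] - b0)
  detected <- amp > k * bsd
  structure(list(detected = detected,
                 amplitude = if (detected) amp else NA_real_,
                 latency_ms = if (detected) t_ms[ipk] else NA_real_,
                 noise_sd = bsd, search_ms = search_ms, k = k),
            class = "vep_result")
}

#' Detect a VEP from a trial matrix
#'
#' Averages the sweeps and applies [detect_vep()] with the noise SD
#' estimated from the pre-stimulus baseline of the individual sweeps
#' (their pooled SD), the level the `k`-fold detection criterion refers
#' to: an averaged response must rise above twice the recording's noise,
#' not above the residual fluctuation of the average itself, which is
#' heavily autocorrelated and would trigger spuriously.
#'
#' @inheritParams detect_vep
#' @param trials samples x trials matrix
#' @param n_sweeps sweeps to average (default all)
#' @return a `vep_result` (see [detect_vep()])
#' @export
vep_from_trials <- function(trials, fs, onset_s, n_sweeps = NULL,
                            search_ms = c(75, 150), baseline_ms = c(-100, 0),
                            k = 2) {
  trials <- as.matrix(trials)
  avg <- average_sweeps(trials, n_sweeps)
  t_ms <- (seq_len(nrow(trials)) - 1) / fs * 1000 - onset_s * 1000
  in_base <- t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]
  sweep_sd <- sqrt(mean(apply(trials[in_base, , drop = FALSE], 2, stats::var)))
  detect_vep(avg, fs, onset_s, search_ms = search_ms,
             baseline_ms = baseline_ms, k = k, noise_sd = sweep_sd)
}

#' Visual acuity from the amplitude decay across spatial frequencies
#'
#' Ordinary least-squares regression of pattern-evoked amplitude on
#' log10(spatial frequency); visual acuity is the extrapolated X-axis
#' intercept `10^(-intercept / slope)`, the spatial frequency at which the
#' response amplitude vanishes. Frequencies without a detected response
#' are dropped from the fit.
#'
#' @param freqs spatial frequencies (cycles/deg), > 0
#' @param amplitudes evoked amplitudes (uV)
#' @param detected optional logical; non-detected points are excluded
#' @return an `acuity_fit`: list with `slope`, `intercept`,
#'   `acuity_c_per_deg`, `r_squared`, `n_points`
#' @export
estimate_acuity <- function(freqs, amplitudes, detected = NULL) {
  stopifnot(length(freqs) == length(amplitudes), all(freqs > 0))
  keep <- detected %||% rep(TRUE, length(freqs))
  freqs <- freqs[keep]; amplitudes <- amplitudes[keep]
  if (length(freqs) < 3)
    stop_retquant("need >= 3 detected frequencies for the acuity fit",
                  "retquant_insufficient_points")
  fit <- lm(amplitudes ~ log10(freqs))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop_retquant("amplitude does not decay with spatial frequency; acuity undefined",
                  "retquant_no_decay")
  ss_tot <- sum((amplitudes - mean(amplitudes))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 acuity_c_per_deg = 10^(-intercept / slope),
                 r_squared = r2,
                 n_points = length(freqs)),
            class = "acuity_fit")
}

#' Time-frequency Z-score map of a peristimulus trace
#'
#' Short-time power spectral density on 5-ms hops (Hann-windowed
#' periodogram, 60-ms segments by default) over the peristimulus window,
#' Z-scored per frequency row against the pre-stimulus bins:
#' `Z(t) = (P(t) - mean(P_baseline)) / sd(P_baseline)`.
#'
#' @param x single-channel trace (numeric vector)
#' @param fs sampling rate (Hz)
#' @param onset_s stimulus onset relative to the first sample (s)
#' @param peristim_s analysis window relative to onset (default
#'   `c(-0.1, 0.4)`)
#' @param bin_s hop between spectral bins (default 0.005)
#' @param segment_s spectral segment length (default 0.060)
#' @return a `zscore_map`: list with `time_s` (bin centres re onset),
#'   `freq_hz`, `z` (freq x time), `power`, `flagged` (frequencies with
#'   zero baseline SD, whose rows are `NA`)
#' @export
spectral_zscore <- function(x, fs, onset_s, peristim_s = c(-0.1, 0.4),
                            bin_s = 0.005, segment_s = 0.060) {
  seg_n <- round(segment_s * fs)
  stopifnot(seg_n >= 8)
  centers <- seq(peristim_s[1], peristim_s[2], by = bin_s)
  n_pre <- sum(centers < 0)
  if (n_pre < 10)
    stop("pre-stimulus interval must contain at least 10 bins")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_n) / (seg_n + 1))  # Hann
  nfreq <- seg_n %/% 2
  P <- matrix(NA_real_, nfreq, length(centers))
  for (j in seq_along(centers)) {
    c_idx <- round((centers[j] + onset_s) * fs) + 1
    idx <- (c_idx - seg_n %/% 2):(c_idx + (seg_n - seg_n %/% 2) - 1)
    if (idx[1] < 1 || idx[length(idx)] > length(x))
      stop("peristimulus window extends outside the trace")
    seg <- x[idx] * win
    sp <- abs(fft(seg))^2 / seg_n
    P[, j] <- sp[2:(nfreq + 1)]
  }
  base <- P[, centers < 0, drop = FALSE]
  mu <- rowMeans(base)
  sdv <- apply(base, 1, sd)
  flagged <- sdv <= 0
  z <- (P - mu) / sdv
  z[flagged, ] <- NA_real_
  structure(list(time_s = centers, freq_hz = (seq_len(nfreq)) * fs / seg_n,
                 z = z, power = P, flagged = which(flagged)),
            class = "zscore_map")
}

#' Peristimulus time histogram
#'
#' Spike counts aligned to stimulus onset, averaged across trials and
#' converted to a firing rate in Hz (10-ms bins across 50 trials in the
#' cortical probe protocol).
#'
#' @param spike_times spike times (s) relative to their trial start
#' @param trial trial index of each spike
#' @param onsets stimulus onset per trial (s; scalar recycled)
#' @param n_trials number of trials averaged over
#' @param bin_s bin width (default 0.010)
#' @param window_s peristimulus window relative to onset
#'   (default `c(-0.1, 0.5)`)
#' @return list with `t_s` (bin left edges re onset), `rate_hz`,
#'   `counts`, `bin_s`, `n_trials`
#' @export
psth <- function(spike_times, trial, onsets, n_trials,
                 bin_s = 0.010, window_s = c(-0.1, 0.5)) {
  stopifnot(length(spike_times) == length(trial), n_trials >= 1)
  if (length(onsets) == 1L) onsets <- rep(onsets, n_trials)
  rel <- spike_times - onsets[trial]
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  nb <- length(edges) - 1L
  keep <- rel >= window_s[1] & rel < edges[nb + 1L]
  idx <- pmin(nb, floor((rel[keep] - window_s[1]) / bin_s) + 1L)
  counts <- tabulate(idx, nbins = nb)
  list(t_s = edges[-length(edges)], rate_hz = counts / n_trials / bin_s,
       counts = counts, bin_s = bin_s, n_trials = n_trials)
}

#' Maximum firing-rate Z-score in the post-stimulus window
#'
#' Smooths the rate trace with a centred boxcar (50 ms window; edges
#' shrink the window rather than pad), Z-scores it against the baseline
#' window mean and SD, and reports the maximum Z inside the response
#' window (default 150-500 ms post-stimulus).
#'
#' @param rate_hz rate trace (e.g. `psth()$rate_hz`)
#' @param t_s time of each sample relative to stimulus onset (s)
#' @param smooth_s boxcar width (default 0.050)
#' @param baseline_s baseline window (default all `t < 0`)
#' @param response_s response window (default `c(0.15, 0.5)`)
#' @return list with `max_z`, `t_max`, `z` (full smoothed Z trace),
#'   `baseline_mean`, `baseline_sd`
#' @export
spiking_zscore <- function(rate_hz, t_s, smooth_s = 0.050,
                           baseline_s = NULL, response_s = c(0.15, 0.5)) {
  stopifnot(length(rate_hz) == length(t_s))
  dt <- stats::median(diff(t_s))
  half <- max(0L, round(smooth_s / dt / 2))
  sm <- boxcar_smooth(rate_hz, half)
  in_base <- if (is.null(baseline_s)) t_s < 0 else
    t_s >= baseline_s[1] & t_s < baseline_s[2]
  if (sum(in_base) < 5) stop("baseline window must contain >= 5 samples")
  mu <- mean(sm[in_base]); sdv <- sd(sm[in_base])
  if (sdv <= 0)
    stop_retquant("degenerate baseline: zero standard deviation",
                  "retquant_degenerate_baseline")
  z <- (sm - mu) / sdv
  in_resp <- t_s >= response_s[1] & t_s <= response_s[2]
  imax <- which(in_resp)[which.max(z[in_resp])]
  list(max_z = z[imax], t_max = t_s[imax], z = z,
       baseline_mean = mu, baseline_sd = sdv)
}

# Centred moving average with window shrinking at the edges (no padding).
boxcar_smooth <- function(x, half) {
  if (half == 0L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Exclude low-rate units
#'
#' Units with a mean firing rate below 0.2 Hz are excluded; a unit at
#' exactly 0.2 Hz is retained (the exclusion is strictly below threshold).
#'
#' @param mean_rates_hz named or unnamed vector of mean unit rates
#' @param min_rate_hz exclusion threshold (default 0.2)
#' @return logical vector: TRUE for retained units
#' @export
filter_units <- function(mean_rates_hz, min_rate_hz = 0.2) {
  stopifnot(all(mean_rates_hz >= 0))
  mean_rates_hz >= min_rate_hz
}
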