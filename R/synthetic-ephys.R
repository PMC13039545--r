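#' Generate a synthetic evoked-potential recording
#'
#' Each trial is 1/f-shaped background noise (white Gaussian noise
#' spectrally shaped to a 1/f amplitude spectrum, the canonical cortical
#' LFP statistic the Z-score baseline assumes) plus a stereotyped
#' Gaussian-shaped deflection of the given amplitude and latency. A
#' companion pattern-series amplitude table follows the semi-log acuity
#' law `A(f) = -slope * (log10 f - log10 acuity)`, clipped at zero, with
#' additive Gaussian noise.
#'
#' @param n_trials number of sweeps (flash protocol: 200; probe: 50)
#' @param fs sampling rate, Hz (>= 1000)
#' @param evoked_amplitude deflection amplitude (uV); 0 = no response
#' @param latency_ms deflection peak latency after onset (ms)
#' @param noise_sd background noise SD (uV)
#' @param acuity_c_per_deg true acuity of the amplitude table (c/deg)
#' @param slope amplitude decay per log10 unit of spatial frequency (uV)
#' @param freqs spatial frequencies of the pattern series (c/deg)
#' @param amp_noise_sd noise SD of the amplitude table (uV)
#' @param prestim_s,poststim_s trial extent around onset (s)
#' @param deflection_sd_ms width (SD) of the Gaussian deflection (ms)
#' @param polarity +1 or -1 (cortical VEPs are negative at depth)
#' @param seed integer seed
#' @return list with `trials` (samples x trials), `t_s` (time re onset),
#'   `fs`, `onset_s`, `amplitude_table` (data frame `freq_c_per_deg`,
#'   `amplitude_uv`), and `truth`
#' @export
generate_vep_recording <- function(n_trials = 200L, fs = 5000,
                                   evoked_amplitude = 50, latency_ms = 100,
                                   noise_sd = 20, acuity_c_per_deg = 0.4,
                                   slope = 20,
                                   freqs = c(0.05, 0.1, 0.2, 0.3),
                                   amp_noise_sd = 0,
                                   prestim_s = 0.2, poststim_s = 0.5,
                                   deflection_sd_ms = 12, polarity = -1,
                                   seed = 1L) {
  if (fs < 1000) stop("fs must be at least 1 kHz")
  stopifnot(n_trials >= 1, noise_sd >= 0, evoked_amplitude >= 0)
  withr::with_seed(seed, {
    n <- round((prestim_s + poststim_s) * fs)
    t_s <- (seq_len(n) - 1) / fs - prestim_s
    deflection <- polarity * evoked_amplitude *
      exp(-(t_s - latency_ms / 1000)^2 / (2 * (deflection_sd_ms / 1000)^2))
    trials <- matrix(0, n, n_trials)
    for (j in seq_len(n_trials)) {
      trials[, j] <- deflection +
        if (noise_sd > 0) one_over_f_noise(n, noise_sd) else 0
    }
    amp <- pmax(0, -slope * (log10(freqs) - log10(acuity_c_per_deg)))
    if (amp_noise_sd > 0) amp <- pmax(0, amp + rnorm(length(freqs), sd = amp_noise_sd))
    list(trials = trials, t_s = t_s, fs = fs, onset_s = prestim_s,
         amplitude_table = data.frame(freq_c_per_deg = freqs, amplitude_uv = amp),
         truth = data.frame(evoked_amplitude = evoked_amplitude,
                            latency_ms = latency_ms,
                            acuity_c_per_deg = acuity_c_per_deg,
                            slope = slope, responder = evoked_amplitude > 0))
  })
}

# White Gaussian noise shaped to a 1/f amplitude spectrum, rescaled to sd.
one_over_f_noise <- function(n, sd_target) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # fold to two-sided frequency magnitude
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_target / sd(x)
}

#' Generate inhomogeneous-Poisson spike trains
#'
#' Per unit and trial, spikes follow a piecewise-constant-rate Poisson
#' process: `baseline_rate_hz` outside the response window and
#' `baseline_rate_hz * gain` inside it.
#'
#' @param n_units number of units
#' @param baseline_rate_hz baseline firing rate (>= 0)
#' @param gain multiplicative rate gain in the response window (1 = none)
#' @param response_window_s window of elevated rate, relative to trial
#'   start (default `c(0.35, 0.7)`, i.e. 150-500 ms after an onset at
#'   0.2 s)
#' @param n_trials trials per unit
#' @param trial_dur_s trial length (s)
#' @param seed integer seed
#' @return list with `spikes` (data frame `unit`, `trial`, `t_s`) and
#'   `truth` (per-unit baseline rate and gain)
#' @export
generate_spike_trains <- function(n_units = 20L, baseline_rate_hz = 10,
                                  gain = 3, response_window_s = c(0.35, 0.7),
                                  n_trials = 50L, trial_dur_s = 1,
                                  seed = 1L) {
  stopifnot(baseline_rate_hz >= 0, gain >= 0, n_units >= 1, n_trials >= 1)
  withr::with_seed(seed, {
    segs <- rbind(c(0, response_window_s[1], baseline_rate_hz),
                  c(response_window_s[1], response_window_s[2], baseline_rate_hz * gain),
                  c(response_window_s[2], trial_dur_s, baseline_rate_hz))
    segs <- segs[segs[, 2] > segs[, 1], , drop = FALSE]
    out <- vector("list", n_units * n_trials)
    k <- 0L
    for (u in seq_len(n_units)) for (tr in seq_len(n_trials)) {
      ts <- unlist(lapply(seq_len(nrow(segs)), function(i) {
        lam <- segs[i, 3] * (segs[i, 2] - segs[i, 1])
        if (lam <= 0) return(numeric(0))
        sort(runif(rpois(1, lam), segs[i, 1], segs[i, 2]))
      }))
      k <- k + 1L
      out[[k]] <- if (length(ts)) data.frame(unit = u, trial = tr, t_s = ts) else NULL
    }
    spikes <- do.call(rbind, out)
    if (is.null(spikes)) spikes <- data.frame(unit = integer(0), trial = integer(0),
                                              t_s = numeric(0))
    list(spikes = spikes,
         truth = data.frame(unit = seq_len(n_units),
                            baseline_rate_hz = baseline_rate_hz, gain = gain,
                            window_lo_s = response_window_s[1],
                            window_hi_s = response_window_s[2]))
  })
}
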