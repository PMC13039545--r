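#' Generate a synthetic behavior state trace
#'
#' Builds a time-stamped categorical state series whose summed state
#' durations equal the requested durations exactly (durations must be
#' multiples of the sample period). For the optomotor protocol the states
#' are concordant / discordant / neither tracking; for conditioning they
#' are freezing / active. Segment order is randomized.
#'
#' @param concordant_s,discordant_s,neither_s state durations (s), OMR mode
#' @param freezing_fraction fraction of the session spent freezing,
#'   conditioning mode (overrides the OMR durations)
#' @param session_s total session duration (s)
#' @param condition condition label carried in the trace (e.g. spatial
#'   frequency or session phase)
#' @param dt_s sample period (default 0.1 s)
#' @param n_segments number of alternating bouts the durations are split
#'   into
#' @param seed integer seed
#' @return a data frame `t_s`, `state`, `condition` (class
#'   `behavior_trace`)
#' @export
generate_behavior_trace <- function(concordant_s = 0, discordant_s = 0,
                                    neither_s = 0, freezing_fraction = NULL,
                                    session_s = NULL, condition = NA,
                                    dt_s = 0.1, n_segments = 10L, seed = 1L) {
  withr::with_seed(seed, {
    if (!is.null(freezing_fraction)) {
      stopifnot(!is.null(session_s), freezing_fraction >= 0, freezing_fraction <= 1)
      freeze_s <- freezing_fraction * session_s
      durations <- c(freezing = freeze_s, active = session_s - freeze_s)
    } else {
      stopifnot(concordant_s >= 0, discordant_s >= 0, neither_s >= 0)
      durations <- c(concordant = concordant_s, discordant = discordant_s,
                     neither = neither_s)
      if (!is.null(session_s) && sum(durations) > session_s + 1e-9)
        stop("state durations exceed the session duration")
    }
    counts <- durations / dt_s
    if (any(abs(counts - round(counts)) > 1e-6))
      stop("durations must be multiples of the sample period dt_s")
    counts <- round(counts)
    # split each state's samples into bouts and interleave them randomly
    bouts <- list()
    for (s in names(counts)) {
      n <- counts[[s]]
      if (n == 0) next
      nb <- min(n_segments, n)
      sizes <- diff(round(seq(0, n, length.out = nb + 1)))
      sizes <- sizes[sizes > 0]
      bouts <- c(bouts, lapply(sizes, function(k) rep(s, k)))
    }
    state <- unlist(bouts[sample.int(length(bouts))], use.names = FALSE)
    out <- data.frame(t_s = seq_along(state) * dt_s - dt_s, state = state,
                      condition = condition, stringsAsFactors = FALSE)
    class(out) <- c("behavior_trace", "data.frame")
    out
  })
}

# Total duration per state of a uniformly sampled trace.
state_durations <- function(trace) {
  dt <- if (nrow(trace) > 1) stats::median(diff(trace$t_s)) else NA_real_
  tapply(rep(dt, nrow(trace)), trace$state, sum, default = 0)
}

#' Optomotor response score
#'
#' The ratio of total concordant to total discordant head/body movement
#' time with respect to the moving gratings; a score of 1.0 is the
#' threshold for visual perception of the tested spatial frequency. Time
#' in neither state is excluded from both numerator and denominator.
#'
#' @param trace a behavior trace (`t_s`, `state`) with states among
#'   concordant / discordant / neither
#' @return the OMR score (dimensionless)
#' @export
omr_score <- function(trace) {
  d <- state_durations(trace)
  conc <- if ("concordant" %in% names(d)) d[["concordant"]] else 0
  disc <- if ("discordant" %in% names(d)) d[["discordant"]] else 0
  if (disc <= 0)
    stop_retquant("no discordant movement time: OMR score undefined (censored high)",
                  "retquant_censored_high")
  conc / disc
}

#' Aggregate OMR scores over repeats of each spatial frequency
#'
#' Per-repeat scores are averaged arithmetically within each condition
#' (each frequency is presented at least four times in the protocol);
#' `pooled = TRUE` instead pools durations before taking the ratio.
#'
#' @param traces list of behavior traces, each with a `condition` column
#' @param pooled pool durations across repeats instead of averaging scores
#' @return data frame `condition`, `score`, `n_repeats`
#' @export
omr_scores <- function(traces, pooled = FALSE) {
  conds <- vapply(traces, function(tr) as.character(tr$condition[1]), "")
  out <- lapply(split(traces, conds), function(trs) {
    if (pooled) {
      tot <- Reduce(`+`, lapply(trs, function(tr) {
        d <- state_durations(tr)
        c(conc = if ("concordant" %in% names(d)) d[["concordant"]] else 0,
          disc = if ("discordant" %in% names(d)) d[["discordant"]] else 0)
      }))
      if (tot[["disc"]] <= 0)
        stop_retquant("no discordant time in pooled repeats", "retquant_censored_high")
      data.frame(score = tot[["conc"]] / tot[["disc"]], n_repeats = length(trs))
    } else {
      data.frame(score = mean(vapply(trs, omr_score, 0)), n_repeats = length(trs))
    }
  })
  data.frame(condition = names(out), do.call(rbind, out), row.names = NULL)
}

#' Percentage of session time spent freezing
#'
#' @param trace a behavior trace with states freezing / active
#' @param session_s session duration (default: trace extent)
#' @return freezing percentage in `[0, 100]`
#' @export
freezing_percentage <- function(trace, session_s = NULL) {
  d <- state_durations(trace)
  freeze <- if ("freezing" %in% names(d)) d[["freezing"]] else 0
  session_s <- session_s %||% sum(d)
  if (is.null(session_s) || session_s <= 0)
    stop("session duration must be positive")
  100 * freeze / session_s
}

#' Summary of a light-cued classical-conditioning session
#'
#' Freezing percentage per protocol phase: the 7 cue-shock pairings of the
#' conditioning day (the learning curve), the cued-recall sub-periods
#' (2-min dark then 3-min conditioned stimulus) with their paired
#' difference, and the 5-min context recall.
#'
#' @param traces named list of behavior traces; required names
#'   `pairing_1` .. `pairing_7`, `cue_dark`, `cue_cs`, `context`
#' @return list with `pairings` (data frame `phase`, `freezing_pct`),
#'   `cue` (dark, CS, and `cs_minus_dark`), `context_pct`
#' @export
conditioning_summary <- function(traces) {
  phases <- c(paste0("pairing_", 1:7), "cue_dark", "cue_cs", "context")
  missing <- setdiff(phases, names(traces))
  if (length(missing) > 0)
    stop(sprintf("missing session phase(s): %s", paste(missing, collapse = ", ")))
  fp <- vapply(phases, function(p) freezing_percentage(traces[[p]]), 0)
  list(pairings = data.frame(phase = phases[1:7], freezing_pct = unname(fp[1:7])),
       cue = c(dark = unname(fp[["cue_dark"]]), cs = unname(fp[["cue_cs"]]),
               cs_minus_dark = unname(fp[["cue_cs"]] - fp[["cue_dark"]])),
       context_pct = unname(fp[["context"]]))
}
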