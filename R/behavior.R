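#' Circular median of clock offsets
#'
#' The circular median is defined here as the sample point minimizing the
#' summed geodesic distance on the cycle (distance between two positions is
#' the shorter way around). Restricting candidates to the sample makes the
#' estimator exactly brute-force testable; ties break to the smallest value.
#'
#' @param values Clock-relative offsets or positions (same cyclic scale).
#' @param cycle Cycle length (ms for offsets, clock units for positions).
#' @return The minimizing sample point.
#' @export
circular_median <- function(values, cycle) {
  if (!length(values)) stop("circular_median: empty input")
  if (length(values) == 1) return(values)
  costs <- vapply(values, function(c0) {
    sum(abs(wrap_half_cycle(values - c0, cycle)))
  }, numeric(1))
  cand <- values[costs <= min(costs) + 1e-12]
  min(cand)
}

# Event time against which a report of the given query is referenced.
query_event_ms <- function(trial, query) {
  switch(query,
    INTENTION = ,
    ACTION = {
      if (!is.na(trial$t_action_ms)) trial$t_action_ms
      else trial$t_decoder_intent_ms
    },
    EFFECT = trial$t_tone_ms,
    NA_real_)
}

#' Per-trial report offsets
#'
#' Converts each reported clock position to the signed offset from the
#' relevant objective event (intention and action reports are referenced to
#' the action time — or the decoder-threshold time on movement-absent trials
#' — and effect reports to the tone), using the nearest-occurrence rule.
#'
#' @param bundle A [session_bundle()].
#' @return Data frame `(trial_id, condition, report_query, offset_ms)`, one
#'   row per reported trial.
#' @export
report_offsets <- function(bundle) {
  trials <- bundle$trials
  keep <- trials$report_query != "NONE" & !is.na(trials$report_units)
  trials <- trials[keep, , drop = FALSE]
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    ev <- query_event_ms(tr, tr$report_query)
    if (is.na(ev)) next
    out[[i]] <- data.frame(
      trial_id = tr$trial_id, condition = tr$condition,
      report_query = tr$report_query,
      offset_ms = report_to_event_relative_time(tr, ev, bundle$config),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(trial_id = character(), condition = character(),
                      report_query = character(), offset_ms = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize clock reports per condition and query
#'
#' One row per (condition, query) present in the session: the circular
#' median of the event-relative offsets and its standard error
#' (`sd/sqrt(n)` of the unwrapped offsets). Condition-query cells with no
#' reported trials are omitted.
#'
#' @param bundle A [session_bundle()].
#' @return Data frame `(condition, query, n, median_offset_ms, sem_ms)`.
#' @export
summarize_reports <- function(bundle) {
  off <- report_offsets(bundle)
  if (!nrow(off))
    return(data.frame(condition = character(), query = character(),
                      n = integer(), median_offset_ms = numeric(),
                      sem_ms = numeric(), stringsAsFactors = FALSE))
  cycle <- bundle$config$clock_cycle_ms
  groups <- split(off, list(off$condition, off$report_query), drop = TRUE)
  rows <- lapply(groups, function(g) {
    data.frame(condition = g$condition[1], query = g$report_query[1],
               n = nrow(g),
               median_offset_ms = circular_median(g$offset_ms, cycle),
               sem_ms = stats::sd(g$offset_ms) / sqrt(nrow(g)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$query), , drop = FALSE]
}

#' Contrast report offsets between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on the (already unwrapped,
#' nearest-event) offsets, the package's default for "targeted
#' non-parametric statistics" on unpaired single-subject trial data.
#'
#' @param offsets_a,offsets_b Event-relative offsets (ms) for the two sides.
#' @param cycle Clock cycle (ms), for the circular medians.
#' @param label_a,label_b Condition labels carried into the result.
#' @param query Report query label carried into the result.
#' @return Data frame row `(condition_a, condition_b, query, delta_ms,
#'   p_value, test_name)`; `delta_ms` = median(a) - median(b).
#' @export
contrast_conditions <- function(offsets_a, offsets_b, cycle = 2560,
                                label_a = "a", label_b = "b",
                                query = NA_character_) {
  if (length(offsets_a) < 2 || length(offsets_b) < 2)
    stop("contrast_conditions: need >= 2 trials per side")
  wt <- stats::wilcox.test(offsets_a, offsets_b, exact = FALSE, correct = TRUE)
  data.frame(condition_a = label_a, condition_b = label_b, query = query,
             delta_ms = circular_median(offsets_a, cycle) -
               circular_median(offsets_b, cycle),
             p_value = wt$p.value, test_name = "wilcoxon_rank_sum",
             stringsAsFactors = FALSE)
}

#' Median pairwise action-effect interval
#'
#' Median over all cross pairs of (effect estimate - action estimate), both
#' expressed on a common timeline. Measures the perceived action-to-tone
#' interval independently of the shared report bias.
#'
#' @param action_estimates,effect_estimates Estimated event times (ms) on a
#'   common reference.
#' @return Median pairwise difference (ms).
#' @export
pairwise_action_effect_median <- function(action_estimates, effect_estimates) {
  if (!length(action_estimates) || !length(effect_estimates))
    stop("pairwise_action_effect_median: empty input")
  stats::median(as.numeric(outer(effect_estimates, action_estimates, `-`)))
}

#' Report timing split by decoder AUC tertiles
#'
#' Sorts trials by their decoder AUC (stable sort, ties broken on
#' `trial_id`), keeps the top and bottom thirds, and compares their report
#' offsets with a rank-sum test. With intention-action binding, high-AUC
#' trials show later intention reports and earlier action reports.
#'
#' @param trials Data frame with columns `trial_id`, `auc`, `offset_ms`.
#' @param query Label carried into the result.
#' @param cycle Clock cycle (ms).
#' @return Data frame row `(query, median_high_auc_ms, median_low_auc_ms,
#'   p_value, n_per_tertile)`.
#' @export
auc_tertile_split <- function(trials, query = NA_character_, cycle = 2560) {
  stopifnot(all(c("trial_id", "auc", "offset_ms") %in% names(trials)))
  if (nrow(trials) < 6)
    stop("auc_tertile_split: need >= 6 trials with AUC and reports")
  ord <- order(trials$auc, trials$trial_id, method = "radix")
  trials <- trials[ord, , drop = FALSE]
  n3 <- as.integer(nrow(trials) %/% 3)
  low <- trials$offset_ms[seq_len(n3)]
  high <- trials$offset_ms[seq(nrow(trials) - n3 + 1, nrow(trials))]
  wt <- stats::wilcox.test(high, low, exact = FALSE, correct = TRUE)
  data.frame(query = query,
             median_high_auc_ms = circular_median(high, cycle),
             median_low_auc_ms = circular_median(low, cycle),
             p_value = wt$p.value, n_per_tertile = n3,
             stringsAsFactors = FALSE)
}

#' Decoder AUC and report offset per trial
#'
#' Convenience assembler for [auc_tertile_split()]: computes the decoder AUC
#' in a window around each trial's anchor event and joins it with the
#' trial's report offset.
#'
#' @param bundle A [session_bundle()].
#' @param query Report query to keep.
#' @param window_ms AUC window around the anchor (default +/- 2,000 ms).
#' @return Data frame `(trial_id, auc, offset_ms)`.
#' @export
trial_auc_offsets <- function(bundle, query, window_ms = c(-2000, 2000)) {
  off <- report_offsets(bundle)
  off <- off[off$report_query == query, , drop = FALSE]
  keep <- off$trial_id %in% names(bundle$decoder)
  off <- off[keep, , drop = FALSE]
  auc <- vapply(off$trial_id, function(id) {
    tr <- bundle$trials[bundle$trials$trial_id == id, ]
    anchor <- trial_anchor_ms(tr)
    trace <- bundle$decoder[[id]]
    tts <- trace_times(trace)
    win <- c(max(min(tts), anchor + window_ms[1]),
             min(max(tts), anchor + window_ms[2]))
    decoder_auc(trace, win)
  }, numeric(1))
  data.frame(trial_id = off$trial_id, auc = as.numeric(auc),
             offset_ms = off$offset_ms, stringsAsFactors = FALSE)
}
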