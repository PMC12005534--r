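#' Trial conditions and report queries
#'
#' The intentional chain has three elements — intention (I), action (A) and
#' environmental effect (E, an auditory tone) — and the experiment enables or
#' disables each, giving six conditions: the full chain `IAE`, action+effect
#' without intention (`AE`, NMES-provoked movement), intention+effect without
#' movement (`IE`, stimulation withheld), intention+action without a tone
#' (`IA`), and the two single-element baselines `A_ONLY` and `E_ONLY`.
#'
#' @format Character vectors of valid condition / query codes.
#' @export
CONDITIONS <- c("IAE", "AE", "IE", "IA", "A_ONLY", "E_ONLY")

#' @rdname CONDITIONS
#' @export
QUERIES <- c("INTENTION", "ACTION", "EFFECT", "NONE")

# Which chain elements each condition carries.
condition_has <- function(condition, element) {
  stopifnot(condition %in% CONDITIONS, element %in% c("I", "A", "E"))
  tab <- list(
    IAE = c("I", "A", "E"), AE = c("A", "E"), IE = c("I", "E"),
    IA = c("I", "A"), A_ONLY = "A", E_ONLY = "E"
  )
  element %in% tab[[condition]]
}

#' Experiment configuration
#'
#' Bundles the clock, sampling and analysis constants of a session. The
#' defaults follow the experimental setup: a Libet-style clock completing a
#' full cycle in 2,560 ms with 60 tick marks, an auditory tone 300 ms after
#' movement onset, 30 kHz raw sampling, 100 ms decoder bins, 1 ms spike bins
#' smoothed with a 50 ms Gaussian kernel, and a five-standard-deviations
#' evoked-onset threshold.
#'
#' @param clock_cycle_ms Duration of a full clock cycle (ms).
#' @param clock_units Number of clock ticks per cycle.
#' @param tone_delay_ms Action-to-tone latency (ms).
#' @param sampling_rate_hz Raw / wideband sampling rate (Hz).
#' @param decoder_bin_ms Decoder output bin width (ms).
#' @param mua_bin_ms Spike binning resolution (ms).
#' @param smoothing_sd_ms SD of the Gaussian rate-smoothing kernel (ms).
#' @param onset_k Evoked-onset threshold in baseline SD multiples.
#' @param rng_seed Integer seed associated with the session.
#' @return An object of class `intent_config`.
#' @export
intent_config <- function(clock_cycle_ms = 2560, clock_units = 60,
                          tone_delay_ms = 300, sampling_rate_hz = 30000,
                          decoder_bin_ms = 100, mua_bin_ms = 1,
                          smoothing_sd_ms = 50, onset_k = 5, rng_seed = 1L) {
  cfg <- list(
    clock_cycle_ms = clock_cycle_ms, clock_units = clock_units,
    tone_delay_ms = tone_delay_ms, sampling_rate_hz = sampling_rate_hz,
    decoder_bin_ms = decoder_bin_ms, mua_bin_ms = mua_bin_ms,
    smoothing_sd_ms = smoothing_sd_ms, onset_k = onset_k,
    rng_seed = as.integer(rng_seed)
  )
  durs <- c("clock_cycle_ms", "tone_delay_ms", "sampling_rate_hz",
            "decoder_bin_ms", "mua_bin_ms", "smoothing_sd_ms")
  for (f in durs) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a positive scalar", f))
  }
  if (cfg$clock_units < 2) stop("clock_units must be >= 2")
  if (cfg$onset_k <= 0) stop("onset_k must be > 0")
  structure(cfg, class = "intent_config")
}

#' Convert clock positions to times and back
#'
#' The clock hand sweeps `clock_units` ticks in `clock_cycle_ms`, so the
#' mapping is linear: `units * clock_cycle_ms / clock_units`.
#'
#' @param units Clock position(s), in `[0, clock_units]`.
#' @param ms Duration(s) in ms, in `[0, clock_cycle_ms]`.
#' @param config An [intent_config()].
#' @return Durations in ms (`clock_units_to_ms`) or clock units
#'   (`clock_ms_to_units`).
#' @export
clock_units_to_ms <- function(units, config) {
  if (any(units < 0 | units > config$clock_units))
    stop("clock position outside [0, clock_units]")
  units * config$clock_cycle_ms / config$clock_units
}

#' @rdname clock_units_to_ms
#' @export
clock_ms_to_units <- function(ms, config) {
  if (any(ms < 0 | ms > config$clock_cycle_ms))
    stop("duration outside [0, clock_cycle_ms]")
  ms * config$clock_units / config$clock_cycle_ms
}

# Wrap an offset onto (-cycle/2, cycle/2].
wrap_half_cycle <- function(x, cycle) {
  w <- x %% cycle
  ifelse(w > cycle / 2, w - cycle, w)
}

#' Event-relative time of a clock report
#'
#' A clock report is a tick position; because trials span several clock
#' cycles, the position recurs every `clock_cycle_ms`. The occurrence nearest
#' the objective event resolves the ambiguity (reports cluster within a
#' second or so of their events), and the returned signed offset
#' `report_time - event_time` is guaranteed to lie in
#' `(-cycle/2, +cycle/2]`.
#'
#' @param trial A single trial: any list/row with `clock_phase_units` and
#'   `report_units`.
#' @param event_time_ms Objective event time, ms from trial start.
#' @param config An [intent_config()].
#' @return Signed offset in ms (negative = report earlier than the event).
#' @export
report_to_event_relative_time <- function(trial, event_time_ms, config) {
  ru <- trial$report_units
  if (is.null(ru) || length(ru) != 1 || is.na(ru)) stop_absent("report_units")
  if (is.null(event_time_ms) || length(event_time_ms) != 1 || is.na(event_time_ms))
    stop_absent("event time")
  if (ru < 0 || ru >= config$clock_units)
    stop("report_units outside [0, clock_units)")
  phase <- trial$clock_phase_units %||% 0
  # first time (>= trial start would be the k = 0 occurrence) at which the
  # hand sits on the reported tick
  base_ms <- ((ru - phase) %% config$clock_units) *
    config$clock_cycle_ms / config$clock_units
  wrap_half_cycle(base_ms - event_time_ms, config$clock_cycle_ms)
}

# -- validation ---------------------------------------------------------------

trial_columns <- c("trial_id", "condition", "report_query", "clock_phase_units",
                   "t_action_ms", "t_tone_ms", "t_decoder_intent_ms",
                   "report_units")

validate_trials <- function(trials, config) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols))
    stop(sprintf("trials table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(trials) == 0) return(invisible(trials))
  bad <- character()
  if (anyDuplicated(trials$trial_id)) bad <- c(bad, "duplicate trial_id")
  if (!all(trials$condition %in% CONDITIONS)) bad <- c(bad, "unknown condition")
  if (!all(trials$report_query %in% QUERIES)) bad <- c(bad, "unknown report_query")
  ph <- trials$clock_phase_units
  if (any(is.na(ph) | ph < 0 | ph >= config$clock_units))
    bad <- c(bad, "clock_phase_units outside [0, clock_units)")
  ru <- trials$report_units
  if (any(!is.na(ru) & (ru < 0 | ru >= config$clock_units)))
    bad <- c(bad, "report_units outside [0, clock_units)")
  # tone delay conservation wherever both action and tone exist (IE trials
  # time the tone from the decoder threshold instead)
  both <- !is.na(trials$t_action_ms) & !is.na(trials$t_tone_ms) &
    trials$condition != "IE"
  if (any(abs(trials$t_tone_ms[both] - trials$t_action_ms[both] -
                config$tone_delay_ms) > 1e-9))
    bad <- c(bad, "t_tone_ms - t_action_ms != tone_delay_ms")
  # condition consistency
  for (i in seq_len(nrow(trials))) {
    cond <- trials$condition[i]
    if (condition_has(cond, "A") && cond != "IE" && is.na(trials$t_action_ms[i]))
      bad <- c(bad, sprintf("trial %s: action condition without t_action_ms",
                            trials$trial_id[i]))
    if (cond %in% c("IE", "E_ONLY") && !is.na(trials$t_action_ms[i]))
      bad <- c(bad, sprintf("trial %s: no-movement condition with t_action_ms",
                            trials$trial_id[i]))
    if (cond == "IE" && is.na(trials$t_decoder_intent_ms[i]))
      bad <- c(bad, sprintf("trial %s: IE trial without t_decoder_intent_ms",
                            trials$trial_id[i]))
    if (condition_has(cond, "E") && is.na(trials$t_tone_ms[i]))
      bad <- c(bad, sprintf("trial %s: effect condition without t_tone_ms",
                            trials$trial_id[i]))
  }
  if (length(bad))
    stop(sprintf("invalid trials table: %s", paste(unique(bad), collapse = "; ")))
  invisible(trials)
}

validate_spikes <- function(spikes, duration_ms = NULL) {
  need <- c("unit_id", "channel", "is_sorted_unit", "spike_time_ms")
  missing_cols <- setdiff(need, names(spikes))
  if (length(missing_cols))
    stop(sprintf("spikes table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(spikes) == 0) return(invisible(spikes))
  if (any(spikes$spike_time_ms < 0)) stop("negative spike times")
  if (!is.null(duration_ms) && any(spikes$spike_time_ms > duration_ms))
    stop("spike times beyond session duration")
  ord <- order(spikes$unit_id)
  by_unit <- split(spikes$spike_time_ms[ord], spikes$unit_id[ord])
  if (any(vapply(by_unit, is.unsorted, logical(1))))
    stop("spike times not nondecreasing within unit")
  invisible(spikes)
}

#' Continuous trace container
#'
#' Wraps decoder output, LFP or raw snippets on a regular time grid. Decoder
#' traces are the movement classifier's score stream: one value per 100 ms
#' bin, bounded in `[-1, 1]`, with zero the movement-triggering threshold.
#'
#' @param kind One of `"DECODER"`, `"LFP"`, `"RAW"`.
#' @param fs_hz Sampling rate in Hz (10 for decoder traces).
#' @param t0_ms Time of the first sample, ms from trial start.
#' @param values Numeric vector (or matrix, channels in columns).
#' @return An object of class `continuous_trace`.
#' @export
continuous_trace <- function(kind, fs_hz, t0_ms, values) {
  kind <- match.arg(kind, c("DECODER", "LFP", "RAW"))
  if (fs_hz <= 0) stop("fs_hz must be > 0")
  v <- if (is.matrix(values)) values else as.numeric(values)
  if (any(!is.finite(v))) stop("trace values must be finite")
  if (kind == "DECODER") {
    offenders <- which(v < -1 | v > 1)
    if (length(offenders))
      stop(sprintf("decoder values outside [-1, 1] at sample(s) %s",
                   paste(utils::head(offenders, 5), collapse = ", ")))
  }
  structure(list(kind = kind, fs_hz = fs_hz, t0_ms = t0_ms, values = values),
            class = "continuous_trace")
}

#' @rdname continuous_trace
#' @param trace A `continuous_trace`.
#' @return `trace_times` returns the sample-start times (ms).
#' @export
trace_times <- function(trace) {
  n <- if (is.matrix(trace$values)) nrow(trace$values) else length(trace$values)
  trace$t0_ms + (seq_len(n) - 1L) * 1000 / trace$fs_hz
}

#' Session bundle
#'
#' One session: configuration, trial table, spike table, per-trial decoder
#' traces and (optionally) per-trial LFP traces.
#'
#' @param config An [intent_config()].
#' @param trials Data frame with the trial schema (see [read_session_bundle()]).
#' @param spikes Data frame `(unit_id, channel, is_sorted_unit, spike_time_ms)`.
#' @param decoder Named list of `continuous_trace` (DECODER), names = trial ids.
#' @param lfp Optional named list of `continuous_trace` (LFP).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(config, trials, spikes = empty_spikes(),
                           decoder = list(), lfp = NULL) {
  stopifnot(inherits(config, "intent_config"))
  validate_trials(trials, config)
  validate_spikes(spikes)
  for (nm in names(decoder)) {
    if (!nm %in% trials$trial_id)
      stop(sprintf("decoder trace references unknown trial '%s'", nm))
    if (decoder[[nm]]$kind != "DECODER") stop("non-decoder trace in decoder slot")
  }
  for (nm in names(lfp)) {
    if (!nm %in% trials$trial_id)
      stop(sprintf("lfp trace references unknown trial '%s'", nm))
  }
  structure(list(config = config, trials = trials, spikes = spikes,
                 decoder = decoder, lfp = lfp),
            class = "session_bundle")
}

#' @rdname session_bundle
#' @export
empty_spikes <- function() {
  data.frame(unit_id = character(), channel = integer(),
             is_sorted_unit = logical(), spike_time_ms = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
#' @method print session_bundle
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d trials, %d spikes (%d units), %d decoder traces%s\n",
              nrow(x$trials), nrow(x$spikes),
              length(unique(x$spikes$unit_id)), length(x$decoder),
              if (length(x$lfp)) sprintf(", %d lfp traces", length(x$lfp)) else ""))
  invisible(x)
}

#' Spike times for one unit
#'
#' @param bundle A [session_bundle()].
#' @param unit_id Unit identifier present in `bundle$spikes`.
#' @return Sorted numeric vector of spike times (ms from session start).
#' @export
unit_spike_times <- function(bundle, unit_id) {
  sort(bundle$spikes$spike_time_ms[bundle$spikes$unit_id == unit_id])
}
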