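#' Synthetic-session generator parameters
#'
#' Defaults emulate the statistical structure of the BMI-NMES intentional
#' chain experiment: six conditions with 50 repetitions each, a 96-channel
#' multi-unit array plus 66 sorted single units firing as inhomogeneous
#' Poisson processes, clock reports with condition-dependent biases
#' (intention reported ~600 ms early, action ~455 ms early, effect ~512 ms
#' early) and dispersions matching the reported standard errors scaled by
#' sqrt(n), a movement decoder trace per trial normalized to `[-1, 1]` with
#' zero-crossing exactly at action, and a single-channel LFP with
#' condition-dependent band-power envelopes.
#'
#' Report dispersions: the study reports standard errors of the medians
#' (37.2 / 21.4 / 17.2 ms for intention / action / effect); trial-level SDs
#' default to S.E.M. x sqrt(50).
#'
#' The subjective intention time is a latent per-trial variable (action time
#' plus condition bias plus noise); the report is a noisy reading of it, and
#' intention-responsive units lock their firing-rate step to the latent time,
#' not to the report.
#'
#' @param n_trials_per_condition Trials per condition (default 50).
#' @param n_channels Multi-unit channels (default 96).
#' @param n_sorted_units Sorted single units (default 66).
#' @param baseline_rate_mean_hz,baseline_rate_shape Gamma draw of per-unit
#'   baseline rate (mean ~5 Hz).
#' @param frac_intent_responsive Fraction of units carrying the intention
#'   step (default 0.3).
#' @param frac_intent_correlated Fraction of sorted units whose pre-movement
#'   spike count co-varies with the latent intention time (default 0.12).
#' @param intent_corr_target Target Pearson r for those units (default 0.5).
#' @param step_amp_mean_hz Mean of the per-unit step amplitude `f_I`.
#' @param step_t0_offset_ms Mean midpoint of the step relative to the latent
#'   subjective intention time (default -108 ms, i.e., the rate rises ~108 ms
#'   before the experienced intention).
#' @param step_alpha_ms Mean steepness scale of the step (default 23 ms;
#'   small = step-like, large = ramp-like).
#' @param step_t0_jitter_sd_ms Per-trial SD of the step midpoint (default 50).
#' @param transient_amp_mean_hz Mean movement-transient amplitude (default 15
#'   Hz, so the channel-average peak is ~20 Hz over a ~5 Hz baseline).
#' @param transient_peak_ms Movement-transient latency to peak (default 373).
#' @param transient_width_ms Gaussian width (SD) of the transient.
#' @param bias_intention_with_action_ms,bias_intention_without_action_ms
#'   Intention-report biases with/without ensuing movement (-597 / -796).
#' @param bias_action_with_intention_ms,bias_action_without_intention_ms
#'   Action-report biases with/without intention (-526 / -355).
#' @param bias_effect_ms Effect-report bias (-512).
#' @param sd_intention_ms,sd_action_ms,sd_effect_ms Trial-level report SDs.
#' @param intention_latent_sd_ms Share of the intention dispersion carried by
#'   the latent intention time (the rest is report-reading noise).
#' @param binding_coef_intention,binding_coef_action,binding_coef_effect
#'   Report shift (ms) per unit of decoder-AUC deviation from the condition's
#'   noiseless reference AUC; the default signs reproduce the binding pattern
#'   (high AUC: intention later, action earlier, effect unchanged).
#' @param decoder_rest_level Resting decoder score (default -0.85).
#' @param decoder_noise_sd Per-bin decoder noise SD (default 0.15).
#' @param decoder_lead_ms Lead of the intention ramp before action (1,100).
#' @param decoder_lead_step Initial score offset at ramp onset (detectable in
#'   ensemble averages, not on single trials).
#' @param decoder_objective_lead_ms Time before action at which the mean ramp
#'   reaches 5 noise SDs above rest (default 70 ms).
#' @param decoder_peak Post-crossing plateau score (default 0.5).
#' @param decoder_gain_sd Per-trial multiplicative gain SD on the positive
#'   lobe (drives AUC variability).
#' @param lfp_fs_hz LFP sampling rate after decimation (default 1000).
#' @param lfp_window_ms LFP window around the trial anchor (default 2500 ms
#'   either side).
#' @param lfp_delta_amp,lfp_alpha_amp,lfp_beta_amp Band oscillation
#'   amplitudes (arbitrary units over the 1/f background).
#' @param lfp_delta_onset_ms Start of the sustained pre-movement delta
#'   envelope on intention trials (default -1000 ms).
#' @param t_action_range_ms Range of action times after trial start.
#' @param post_action_ms Trial tail after the anchor event.
#' @param with_spikes,with_decoder,with_lfp Toggles for the heavier session
#'   components (all TRUE at study scale).
#' @param tone_delay_ms Action-to-tone latency (default 300 ms).
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(
    n_trials_per_condition = 50,
    n_channels = 96,
    n_sorted_units = 66,
    baseline_rate_mean_hz = 5, baseline_rate_shape = 2,
    frac_intent_responsive = 0.3,
    frac_intent_correlated = 0.12,
    intent_corr_target = 0.5,
    step_amp_mean_hz = 8,
    step_t0_offset_ms = -108,
    step_alpha_ms = 23,
    step_t0_jitter_sd_ms = 50,
    transient_amp_mean_hz = 15,
    transient_peak_ms = 373,
    transient_width_ms = 120,
    bias_intention_with_action_ms = -597,
    bias_intention_without_action_ms = -796,
    bias_action_with_intention_ms = -526,
    bias_action_without_intention_ms = -355,
    bias_effect_ms = -512,
    sd_intention_ms = 37.2 * sqrt(50),
    sd_action_ms = 21.4 * sqrt(50),
    sd_effect_ms = 17.2 * sqrt(50),
    intention_latent_sd_ms = 200,
    binding_coef_intention = 3000,
    binding_coef_action = -1500,
    binding_coef_effect = 0,
    decoder_rest_level = -0.85,
    decoder_noise_sd = 0.15,
    decoder_lead_ms = 1100,
    decoder_lead_step = 0.15,
    decoder_objective_lead_ms = 70,
    decoder_peak = 0.5,
    decoder_gain_sd = 0.2,
    lfp_fs_hz = 1000,
    lfp_window_ms = 2500,
    lfp_delta_amp = 2, lfp_alpha_amp = 1.5, lfp_beta_amp = 1,
    lfp_delta_onset_ms = -1000,
    t_action_range_ms = c(4000, 8000),
    post_action_ms = 3000,
    with_spikes = TRUE, with_decoder = TRUE, with_lfp = TRUE,
    tone_delay_ms = 300) {
  p <- as.list(environment())
  for (f in c("frac_intent_responsive", "frac_intent_correlated")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(sprintf("%s must be in [0, 1]", f))
  }
  for (f in c("baseline_rate_mean_hz", "step_amp_mean_hz", "transient_amp_mean_hz"))
    if (p[[f]] < 0) stop(sprintf("%s must be >= 0", f))
  for (f in c("step_alpha_ms", "sd_intention_ms", "sd_action_ms",
              "sd_effect_ms", "decoder_noise_sd"))
    if (p[[f]] <= 0) stop(sprintf("%s must be > 0", f))
  if (p$intention_latent_sd_ms >= p$sd_intention_ms)
    stop("intention_latent_sd_ms must be below the total intention SD")
  if (abs(p$intent_corr_target) >= 1) stop("intent_corr_target must be in (-1, 1)")
  structure(p, class = "generator_params")
}

condition_queries <- function(condition) {
  switch(condition,
    IAE = c("INTENTION", "ACTION", "EFFECT"),
    AE = c("ACTION", "EFFECT"),
    IE = c("INTENTION", "EFFECT"),
    IA = c("INTENTION", "ACTION"),
    A_ONLY = "ACTION",
    E_ONLY = "EFFECT")
}

#' Anchor event of a trial
#'
#' The alignment event used throughout the analyses: the action time, or the
#' decoder-threshold time for movement-absent intention trials, or the tone
#' for tone-only trials.
#'
#' @param trial A single trial row.
#' @return Anchor time (ms, trial-relative).
#' @export
trial_anchor_ms <- function(trial) {
  if (!is.na(trial$t_action_ms)) return(trial$t_action_ms)
  if (!is.na(trial$t_decoder_intent_ms)) return(trial$t_decoder_intent_ms)
  trial$t_tone_ms
}

# -- unit population ----------------------------------------------------------

#' Draw a synthetic unit population
#'
#' @param params A [generator_params()].
#' @param n Number of units to draw.
#' @param is_sorted Whether these rows model sorted single units (eligible
#'   for the intention-correlated property) or channel-level multi-units.
#' @return Data frame of per-unit generative parameters.
#' @export
draw_unit_specs <- function(params, n, is_sorted = TRUE) {
  if (n == 0) {
    return(data.frame(unit_id = character(), channel = integer(),
                      is_sorted_unit = logical(), baseline_hz = numeric(),
                      responsive = logical(), f_I = numeric(),
                      t0_offset_ms = numeric(), alpha_ms = numeric(),
                      transient_amp_hz = numeric(), corr_beta = numeric()))
  }
  baseline <- stats::rgamma(n, shape = params$baseline_rate_shape,
                            scale = params$baseline_rate_mean_hz /
                              params$baseline_rate_shape)
  responsive <- stats::runif(n) < params$frac_intent_responsive
  f_I <- stats::rgamma(n, shape = 4, scale = params$step_amp_mean_hz / 4)
  t0_offset <- stats::rnorm(n, params$step_t0_offset_ms, 30)
  alpha <- stats::rgamma(n, shape = 4, scale = params$step_alpha_ms / 4)
  amp <- stats::rgamma(n, shape = 4, scale = params$transient_amp_mean_hz / 4)
  correlated <- is_sorted & stats::runif(n) < params$frac_intent_correlated
  # beta = spikes per SD of latent intention time such that
  # corr(count, latent) ~ target r against Poisson count variance
  r <- params$intent_corr_target
  expected_var <- pmax(baseline, 0.5) # ~1 s pre-movement window
  beta <- ifelse(correlated, sign(r) * sqrt(expected_var * r^2 / (1 - r^2)), 0)
  data.frame(
    unit_id = sprintf(if (is_sorted) "u%03d" else "ch%02d", seq_len(n)),
    channel = if (is_sorted) ((seq_len(n) - 1L) %% 96L) + 1L else seq_len(n),
    is_sorted_unit = is_sorted, baseline_hz = baseline,
    responsive = responsive, f_I = f_I, t0_offset_ms = t0_offset,
    alpha_ms = alpha, transient_amp_hz = amp, corr_beta = beta,
    stringsAsFactors = FALSE)
}

# -- firing-rate model --------------------------------------------------------

#' Generative firing-rate profile for one unit on one trial
#'
#' rate(t) = baseline
#'   + f_I / (1 + exp(-(t - t0) / alpha))     (intention step, if responsive)
#'   + A * exp(-(t - t_action - peak)^2 / 2w^2)  (movement transient)
#'   + beta * z * boxcar(anchor - 1000, anchor)  (intention-correlated gain)
#' floored at zero.
#'
#' @param unit_spec One row of [draw_unit_specs()].
#' @param trial Trial row carrying `t_action_ms`, `t_decoder_intent_ms`,
#'   `duration_ms` and the latent fields `t_sub_intent_ms` / `z_intent`.
#' @param params A [generator_params()].
#' @param t_ms Times (ms, trial-relative) at which to evaluate the rate.
#' @param t0_jitter_ms Per-trial jitter added to the step midpoint.
#' @return Rate in Hz at each `t_ms`.
#' @export
unit_rate_at <- function(unit_spec, trial, params, t_ms, t0_jitter_ms = 0) {
  rate <- rep(unit_spec$baseline_hz, length(t_ms))
  has_intent <- condition_has(trial$condition, "I")
  if (has_intent && isTRUE(unit_spec$responsive) &&
      !is.na(trial$t_sub_intent_ms)) {
    t0 <- trial$t_sub_intent_ms + unit_spec$t0_offset_ms + t0_jitter_ms
    rate <- rate + unit_spec$f_I /
      (1 + exp(-(t_ms - t0) / unit_spec$alpha_ms))
  }
  if (!is.na(trial$t_action_ms)) {
    rate <- rate + unit_spec$transient_amp_hz *
      exp(-0.5 * ((t_ms - trial$t_action_ms - params$transient_peak_ms) /
                    params$transient_width_ms)^2)
  }
  if (has_intent && unit_spec$corr_beta != 0 && !is.na(trial$z_intent)) {
    anchor <- trial_anchor_ms(trial)
    inwin <- t_ms >= anchor - 1000 & t_ms < anchor
    rate[inwin] <- rate[inwin] + unit_spec$corr_beta * trial$z_intent
  }
  pmax(rate, 0)
}

#' Inhomogeneous Poisson spike train by thinning
#'
#' Draws a homogeneous Poisson process at the profile's upper bound and keeps
#' each candidate spike with probability `rate(t) / rate_max`.
#'
#' @inheritParams unit_rate_at
#' @return Sorted spike times (ms, trial-relative).
#' @export
generate_spike_train <- function(unit_spec, trial, params) {
  dur <- trial$duration_ms
  t0_jit <- if (isTRUE(unit_spec$responsive))
    stats::rnorm(1, 0, params$step_t0_jitter_sd_ms) else 0
  lmax <- unit_spec$baseline_hz + unit_spec$f_I + unit_spec$transient_amp_hz +
    abs(unit_spec$corr_beta) * 4 + 1e-9
  n <- stats::rpois(1, lmax * dur / 1000)
  if (n == 0) return(numeric(0))
  tt <- sort(stats::runif(n, 0, dur))
  lam <- unit_rate_at(unit_spec, trial, params, tt, t0_jit)
  if (any(lam < 0)) stop("negative rate profile")
  if (any(lam > lmax + 1e-9)) stop("rate profile exceeds thinning bound")
  tt[stats::runif(n) < lam / lmax]
}

# -- decoder traces -----------------------------------------------------------

# Noiseless mean decoder profile (trial-relative times). Intended trials:
# rest until anchor - lead; small step + slow linear rise reaching 5 noise
# SDs above rest `objective_lead_ms` before the anchor; zero exactly at the
# anchor; fast rise to the plateau; condition-dependent offset/decay.
decoder_mean_profile <- function(condition, anchor_ms, t_ms, params) {
  rest <- params$decoder_rest_level
  thr5 <- rest + 5 * params$decoder_noise_sd
  peak <- params$decoder_peak
  rel <- t_ms - anchor_ms
  v <- rep(rest, length(t_ms))
  nodes <- if (condition_has(condition, "I") &&
               params$decoder_lead_ms > params$decoder_objective_lead_ms) {
    rbind(c(-params$decoder_lead_ms, rest + params$decoder_lead_step),
          c(-params$decoder_objective_lead_ms, thr5),
          c(0, 0), c(100, peak))
  } else if (condition_has(condition, "A") ||
             condition_has(condition, "I")) {
    rbind(c(-200, rest), c(0, 0), c(100, peak)) # abrupt NMES-evoked rise
  } else {
    return(v) # E_ONLY: decoder stays at rest
  }
  decay_start <- switch(condition, IE = 100, IA = 1200, 500)
  nodes <- rbind(nodes, c(decay_start, peak), c(decay_start + 400, rest))
  inside <- rel >= nodes[1, 1] & rel <= nodes[nrow(nodes), 1]
  v[inside] <- stats::approx(nodes[, 1], nodes[, 2], xout = rel[inside],
                             ties = "ordered")$y
  v
}

#' Generate one per-trial decoder trace
#'
#' Values are the mean profile for the trial's condition plus Gaussian bin
#' noise, with a per-trial multiplicative gain on the positive (post-
#' crossing) lobe, clipped to `[-1, 1]`. On intended trials the first
#' zero-crossing falls exactly at the action time by construction.
#'
#' @inheritParams unit_rate_at
#' @return A `continuous_trace` of kind `"DECODER"` (10 Hz).
#' @export
generate_decoder_trace <- function(trial, params) {
  bin <- 100
  n_bins <- floor(trial$duration_ms / bin)
  t_ms <- (seq_len(n_bins) - 1L) * bin
  anchor <- trial_anchor_ms(trial)
  mean_v <- if (trial$condition == "E_ONLY")
    rep(params$decoder_rest_level, n_bins)
  else decoder_mean_profile(trial$condition, anchor, t_ms, params)
  gain <- max(0.2, stats::rnorm(1, 1, params$decoder_gain_sd))
  pos <- mean_v > 0
  v <- mean_v
  v[pos] <- mean_v[pos] * gain
  noise <- stats::rnorm(n_bins, 0, params$decoder_noise_sd)
  # keep the pre-crossing contract exact: no noise on the bins from ramp
  # start to the crossing bin on intended/acted trials
  if (trial$condition != "E_ONLY") {
    guard <- t_ms >= anchor - 300 & t_ms <= anchor
    noise[guard] <- 0
    noise[!guard & v + noise >= 0 & t_ms < anchor] <-
      -abs(noise[!guard & v + noise >= 0 & t_ms < anchor]) - 0.01
  }
  v <- pmin(1, pmax(-1, v + noise))
  continuous_trace("DECODER", 1000 / bin, 0, v)
}

# -- LFP ----------------------------------------------------------------------

# 1/f (pink) background noise via spectral shaping.
pink_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + fs / n)
  spec <- spec / sqrt(pmax(f, fs / n))
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate one per-trial LFP trace
#'
#' A 1/f background plus band-limited oscillations whose envelopes follow
#' the condition rules: a sustained delta (2 Hz) envelope from
#' `lfp_delta_onset_ms` before the anchor when intention is present, and a
#' transient alpha (10 Hz) + beta (20 Hz) envelope after movement when an
#' action occurs. One array-average channel.
#'
#' @inheritParams unit_rate_at
#' @return A `continuous_trace` of kind `"LFP"`.
#' @export
generate_lfp <- function(trial, params) {
  fs <- params$lfp_fs_hz
  w <- params$lfp_window_ms
  anchor <- trial_anchor_ms(trial)
  t0 <- anchor - w
  n <- round(2 * w * fs / 1000)
  t_rel <- (seq_len(n) - 1L) * 1000 / fs - w # ms relative to anchor
  x <- pink_noise(n, fs) * 3
  sec <- t_rel / 1000
  if (condition_has(trial$condition, "I")) {
    env <- as.numeric(t_rel >= params$lfp_delta_onset_ms & t_rel <= 500)
    env <- conv_same(env, gaussian_kernel_ms(100, 1000 / fs))
    x <- x + params$lfp_delta_amp * env * sin(2 * pi * 2 * sec +
                                                stats::runif(1, 0, 2 * pi))
  }
  if (condition_has(trial$condition, "A")) {
    # movement induces a post-onset alpha/beta transient (IE trials never
    # move, so none there)
    env <- exp(-0.5 * ((t_rel - 330) / 180)^2)
    x <- x + params$lfp_alpha_amp * env *
      sin(2 * pi * 10 * sec + stats::runif(1, 0, 2 * pi)) +
      params$lfp_beta_amp * env *
      sin(2 * pi * 20 * sec + stats::runif(1, 0, 2 * pi))
  }
  continuous_trace("LFP", fs, t0, x)
}

# -- reports ------------------------------------------------------------------

report_bias_ms <- function(condition, query, params) {
  switch(query,
    INTENTION = if (condition_has(condition, "A"))
      params$bias_intention_with_action_ms
    else params$bias_intention_without_action_ms,
    ACTION = if (condition_has(condition, "I"))
      params$bias_action_with_intention_ms
    else params$bias_action_without_intention_ms,
    EFFECT = params$bias_effect_ms,
    stop_absent("report for query NONE"))
}

binding_coef <- function(query, params) {
  switch(query,
    INTENTION = params$binding_coef_intention,
    ACTION = params$binding_coef_action,
    EFFECT = params$binding_coef_effect)
}

#' Generate a clock report for one trial
#'
#' The report time is the queried event plus the condition/query bias, plus
#' an AUC-dependent binding shift, plus Gaussian noise, wrapped onto the
#' clock. Intention reports read the trial's latent subjective intention
#' time (bias and latent noise already applied) with additional reading
#' noise.
#'
#' @inheritParams unit_rate_at
#' @param query `"INTENTION"`, `"ACTION"` or `"EFFECT"`.
#' @param auc_dev Decoder-AUC deviation from the condition reference (0 when
#'   no decoder trace exists).
#' @param config An [intent_config()] (for the clock geometry).
#' @return List with `report_units` and the underlying `report_time_ms`.
#' @export
generate_report <- function(trial, query, params, config, auc_dev = 0) {
  if (query == "NONE") stop_absent("report for query NONE")
  shift <- binding_coef(query, params) * auc_dev
  t_rep <- switch(query,
    INTENTION = {
      if (is.na(trial$t_sub_intent_ms)) stop_absent("latent intention time")
      read_sd <- sqrt(params$sd_intention_ms^2 - params$intention_latent_sd_ms^2)
      trial$t_sub_intent_ms + shift + stats::rnorm(1, 0, read_sd)
    },
    ACTION = {
      if (is.na(trial$t_action_ms)) stop_absent("t_action_ms")
      trial$t_action_ms + report_bias_ms(trial$condition, "ACTION", params) +
        shift + stats::rnorm(1, 0, params$sd_action_ms)
    },
    EFFECT = {
      if (is.na(trial$t_tone_ms)) stop_absent("t_tone_ms")
      trial$t_tone_ms + report_bias_ms(trial$condition, "EFFECT", params) +
        shift + stats::rnorm(1, 0, params$sd_effect_ms)
    })
  units <- (trial$clock_phase_units +
              t_rep * config$clock_units / config$clock_cycle_ms) %%
    config$clock_units
  list(report_units = units, report_time_ms = t_rep)
}

# -- session assembly ---------------------------------------------------------

#' Generate a complete synthetic session
#'
#' Deterministic given `(params, seed)`. Emits all six conditions with the
#' report query varied in mini-runs of five trials, lays trials back-to-back
#' on a session timeline, and attaches spikes, decoder traces and LFP
#' according to the toggles in `params`. Ground-truth latent variables
#' (subjective intention times, decoder AUC deviations) are attached as the
#' `"truth"` attribute for use in recovery tests; they are not part of the
#' persisted bundle.
#'
#' @param params A [generator_params()].
#' @param seed Integer seed.
#' @param config An [intent_config()].
#' @return A [session_bundle()].
#' @export
generate_session <- function(params = generator_params(), seed = 1L,
                             config = intent_config(rng_seed = seed)) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(seed, generate_session_impl(params, config))
}

generate_session_impl <- function(params, config) {
  n_per <- params$n_trials_per_condition
  rows <- list()
  k <- 0L
  for (cond in CONDITIONS) {
    queries <- condition_queries(cond)
    if (n_per == 0) next
    # mini-runs of 5 trials per report type
    runs <- rep(queries, length.out = ceiling(n_per / 5))
    qseq <- rep(runs, each = 5)[seq_len(n_per)]
    for (i in seq_len(n_per)) {
      k <- k + 1L
      t_anchor <- round(stats::runif(1, params$t_action_range_ms[1],
                                     params$t_action_range_ms[2]) / 100) * 100
      has_a <- condition_has(cond, "A")
      has_i <- condition_has(cond, "I")
      has_e <- condition_has(cond, "E")
      t_action <- if (has_a) t_anchor else NA_real_
      t_dec <- if (has_i) t_anchor else NA_real_
      t_tone <- if (has_e) t_anchor + params$tone_delay_ms else NA_real_
      if (cond == "E_ONLY") t_tone <- t_anchor
      z <- if (has_i) stats::rnorm(1) else NA_real_
      t_sub <- if (has_i)
        t_anchor + report_bias_ms(cond, "INTENTION", params) +
          z * params$intention_latent_sd_ms
      else NA_real_
      rows[[k]] <- data.frame(
        trial_id = sprintf("t%04d", k), condition = cond,
        report_query = qseq[i],
        clock_phase_units = stats::runif(1, 0, config$clock_units),
        t_action_ms = t_action, t_tone_ms = t_tone,
        t_decoder_intent_ms = t_dec, report_units = NA_real_,
        t_start_ms = NA_real_,
        duration_ms = t_anchor + params$post_action_ms,
        t_sub_intent_ms = t_sub, z_intent = z,
        stringsAsFactors = FALSE)
    }
  }
  trials <- if (k > 0) do.call(rbind, rows) else
    cbind(data.frame(trial_id = character(), condition = character(),
                     report_query = character(), clock_phase_units = numeric(),
                     t_action_ms = numeric(), t_tone_ms = numeric(),
                     t_decoder_intent_ms = numeric(), report_units = numeric(),
                     t_start_ms = numeric(), duration_ms = numeric(),
                     t_sub_intent_ms = numeric(), z_intent = numeric(),
                     stringsAsFactors = FALSE))
  if (k > 0) {
    trials$t_start_ms <- cumsum(c(0, utils::head(trials$duration_ms, -1)))
  }

  # decoder traces + AUC deviations (needed before reports for binding)
  decoder <- list()
  auc_dev <- stats::setNames(rep(0, nrow(trials)), trials$trial_id)
  if (params$with_decoder && k > 0) {
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      trace <- generate_decoder_trace(tr, params)
      decoder[[tr$trial_id]] <- trace
      if (tr$condition != "E_ONLY") {
        anchor <- trial_anchor_ms(tr)
        win <- c(max(0, anchor - 2000), min(tr$duration_ms - 100, anchor + 2000))
        ref_trace <- continuous_trace("DECODER", trace$fs_hz, 0,
          decoder_mean_profile(tr$condition, anchor, trace_times(trace), params))
        auc_dev[tr$trial_id] <- decoder_auc(trace, win) -
          decoder_auc(ref_trace, win)
      }
    }
  }

  # reports
  for (i in seq_len(nrow(trials))) {
    q <- trials$report_query[i]
    if (q == "NONE") next
    rep_i <- generate_report(trials[i, ], q, params, config,
                             auc_dev = auc_dev[trials$trial_id[i]])
    trials$report_units[i] <- rep_i$report_units
  }

  # spikes
  spikes <- empty_spikes()
  unit_specs <- NULL
  if (params$with_spikes && k > 0) {
    specs_mua <- draw_unit_specs(params, params$n_channels, is_sorted = FALSE)
    specs_su <- draw_unit_specs(params, params$n_sorted_units, is_sorted = TRUE)
    unit_specs <- rbind(specs_mua, specs_su)
    acc <- vector("list", nrow(unit_specs))
    for (u in seq_len(nrow(unit_specs))) {
      us <- unit_specs[u, ]
      times_u <- vector("list", nrow(trials))
      for (i in seq_len(nrow(trials))) {
        st <- generate_spike_train(us, trials[i, ], params)
        if (length(st)) times_u[[i]] <- st + trials$t_start_ms[i]
      }
      tt <- unlist(times_u)
      if (length(tt))
        acc[[u]] <- data.frame(unit_id = us$unit_id, channel = us$channel,
                               is_sorted_unit = us$is_sorted_unit,
                               spike_time_ms = tt, stringsAsFactors = FALSE)
    }
    acc <- acc[!vapply(acc, is.null, logical(1))]
    if (length(acc)) spikes <- do.call(rbind, acc)
  }

  # lfp
  lfp <- NULL
  if (params$with_lfp && k > 0) {
    lfp <- list()
    for (i in seq_len(nrow(trials))) {
      lfp[[trials$trial_id[i]]] <- generate_lfp(trials[i, ], params)
    }
  }

  truth <- trials[, c("trial_id", "condition", "report_query",
                      "t_sub_intent_ms", "z_intent")]
  truth$auc_dev <- auc_dev[trials$trial_id]
  out_trials <- trials[, c(trial_columns, "t_start_ms", "duration_ms")]
  bundle <- session_bundle(config, out_trials, spikes, decoder, lfp)
  attr(bundle, "truth") <- truth
  attr(bundle, "unit_specs") <- unit_specs
  bundle
}

#' Generate a raw wideband snippet
#'
#' Band-limited noise plus injected multi-unit energy in the 235 Hz -
#' 3.75 kHz band, for exercising the artifact-blanking and wavelet-feature
#' stages; full-rate full-session raw data is unnecessary for the analyses.
#'
#' @param n_channels Number of channels.
#' @param duration_ms Snippet duration.
#' @param fs_hz Sampling rate (default 30 kHz).
#' @param mua_burst_times_ms Times at which multi-unit energy bursts are
#'   injected on all channels.
#' @param mua_amp Burst amplitude (uV).
#' @param noise_sd Background noise SD (uV).
#' @return Matrix (samples x channels), in uV.
#' @export
generate_raw_snippet <- function(n_channels = 12, duration_ms = 1000,
                                 fs_hz = 30000, mua_burst_times_ms = numeric(),
                                 mua_amp = 60, noise_sd = 20) {
  n <- round(duration_ms * fs_hz / 1000)
  x <- matrix(stats::rnorm(n * n_channels, 0, noise_sd), n, n_channels)
  if (length(mua_burst_times_ms)) {
    tt <- (seq_len(n) - 1) / fs_hz * 1000
    carrier <- sin(2 * pi * 1000 * tt / 1000)
    for (bt in mua_burst_times_ms) {
      env <- exp(-0.5 * ((tt - bt) / 5)^2)
      x <- x + mua_amp * env * carrier
    }
  }
  x
}
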