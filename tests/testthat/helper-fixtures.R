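# Shared fixtures, built in code. Small sessions keep the suite fast; the
# generator's study-scale defaults are exercised where a test needs them.

small_params <- function(...) {
  generator_params(n_trials_per_condition = 6, n_channels = 4,
                   n_sorted_units = 4, with_lfp = FALSE, ...)
}

# lazily built shared small session
.fixture_env <- new.env()
small_session <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_session(small_params(), seed = 101L)
  }
  .fixture_env$bundle
}

# independent brute-force circular distance / median oracle
circ_dist_oracle <- function(a, b, cycle) {
  d <- abs(a - b) %% cycle
  pmin(d, cycle - d)
}

circular_median_oracle <- function(values, cycle) {
  cost <- vapply(values, function(c0)
    sum(circ_dist_oracle(values, c0, cycle)), numeric(1))
  min(values[cost <= min(cost) + 1e-12])
}

# a one-row trial "record" convenient for unit-level operations
make_trial <- function(condition = "IAE", t_action = 5000,
                       phase = 0, report = NA_real_, duration = 8000,
                       t_sub = NA_real_, z = NA_real_) {
  has_a <- condition %in% c("IAE", "AE", "IA", "A_ONLY")
  has_i <- condition %in% c("IAE", "IE", "IA")
  has_e <- condition %in% c("IAE", "AE", "IE", "E_ONLY")
  data.frame(trial_id = "t0001", condition = condition,
             report_query = "NONE", clock_phase_units = phase,
             t_action_ms = if (has_a) t_action else NA_real_,
             t_tone_ms = if (has_e) t_action + 300 else NA_real_,
             t_decoder_intent_ms = if (has_i) t_action else NA_real_,
             report_units = report, t_start_ms = 0, duration_ms = duration,
             t_sub_intent_ms = t_sub, z_intent = z,
             stringsAsFactors = FALSE)
}
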