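test_that("generation is deterministic and respects the design counts", {
  p <- small_params()
  b1 <- generate_session(p, seed = 5L)
  b2 <- generate_session(p, seed = 5L)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$spikes, b2$spikes)
  expect_identical(b1$decoder, b2$decoder)
  b3 <- generate_session(p, seed = 6L)
  expect_false(identical(b1$trials$report_units, b3$trials$report_units))

  counts <- table(b1$trials$condition)
  expect_true(all(counts == p$n_trials_per_condition))
  expect_setequal(names(counts), CONDITIONS)
  # report queries vary in runs of 5 within condition
  iae <- b1$trials[b1$trials$condition == "IAE", ]
  expect_true(all(tapply(iae$report_query, (seq_len(nrow(iae)) - 1) %/% 5,
                         function(q) length(unique(q))) == 1))
})

test_that("tone follows action by the configured delay wherever both exist", {
  b <- small_session()
  tr <- b$trials
  both <- !is.na(tr$t_action_ms) & !is.na(tr$t_tone_ms)
  expect_true(any(both))
  expect_equal(tr$t_tone_ms[both] - tr$t_action_ms[both],
               rep(300, sum(both)))
  # IE trials time the tone from the decoder-threshold event instead
  ie <- tr[tr$condition == "IE", ]
  expect_equal(ie$t_tone_ms - ie$t_decoder_intent_ms, rep(300, nrow(ie)))
})

test_that("report model reproduces configured biases and maps back exactly when noiseless", {
  cfg <- intent_config()
  # zero bias, (near-)zero noise: report recovers the event time
  p0 <- generator_params(bias_action_with_intention_ms = 0,
                         sd_action_ms = 1e-9)
  tr <- make_trial("IA", t_action = 5000, phase = 12.3)
  set.seed(1)
  rep0 <- generate_report(tr, "ACTION", p0, cfg)
  tr$report_units <- rep0$report_units
  expect_equal(report_to_event_relative_time(tr, 5000, cfg), 0,
               tolerance = 1e-6)

  # Monte-Carlo: configured -455 ms bias, sigma = 100
  p1 <- generator_params(bias_action_with_intention_ms = -455,
                         sd_action_ms = 100)
  set.seed(2)
  offs <- replicate(4000, {
    t0 <- make_trial("IA", t_action = 5000, phase = runif(1, 0, 60))
    r <- generate_report(t0, "ACTION", p1, cfg)
    t0$report_units <- r$report_units
    report_to_event_relative_time(t0, 5000, cfg)
  })
  expect_equal(median(offs), -455, tolerance = 10)
  expect_error(generate_report(make_trial(), "NONE", p1, cfg), "absent")
})

test_that("spike trains are inhomogeneous Poisson realizations of the profile", {
  p <- generator_params()
  # constant-rate unit: count and ISI statistics match the closed form
  us <- data.frame(unit_id = "u", channel = 1L, is_sorted_unit = TRUE,
                   baseline_hz = 10, responsive = FALSE, f_I = 0,
                   t0_offset_ms = 0, alpha_ms = 20, transient_amp_hz = 0,
                   corr_beta = 0)
  tr <- make_trial("E_ONLY", duration = 100000)
  tr$t_tone_ms <- 50000
  set.seed(3)
  st <- generate_spike_train(us, tr, p)
  expect_true(abs(length(st) - 1000) < 3 * sqrt(1000))
  ks <- suppressWarnings(ks.test(diff(st), "pexp", rate = 0.01))
  expect_gt(ks$p.value, 0.01)

  # zero rate: empty train
  us0 <- us; us0$baseline_hz <- 0; us0$transient_amp_hz <- 0; us0$f_I <- 0
  expect_length(generate_spike_train(us0, tr, p), 0)

  # PSTH of a stepped unit recovers the generating profile within the
  # pointwise Poisson band
  us1 <- us
  us1$responsive <- TRUE; us1$f_I <- 15; us1$alpha_ms <- 20
  us1$t0_offset_ms <- 0
  p1 <- generator_params(step_t0_jitter_sd_ms = 1e-9)
  tr1 <- make_trial("IA", t_action = 4000, duration = 7000,
                    t_sub = 3500, z = 0)
  set.seed(4)
  n_rep <- 150
  rates <- sapply(seq_len(n_rep), function(i) {
    st <- generate_spike_train(us1, tr1, p1)
    bin_and_smooth(st, c(1000, 6000), sd_ms = 50)$rate_hz
  })
  psth <- rowMeans(rates)
  t_grid <- bin_and_smooth(numeric(), c(1000, 6000))$t_ms
  truth <- unit_rate_at(us1, tr1, p1, t_grid)
  kern <- intentchain:::gaussian_kernel_ms(50, 1)
  pad <- (length(kern) - 1) / 2
  truth_ext <- unit_rate_at(us1, tr1, p1,
                            seq(1000 - pad, 6000 - 1 + pad, by = 1))
  truth_sm <- stats::convolve(truth_ext, rev(kern), type = "filter")
  se <- sqrt(truth_sm * 1000 * sum(kern^2) / n_rep)
  inside <- abs(psth - truth_sm) < 4 * se + 0.5
  expect_gt(mean(inside), 0.99)
})

test_that("decoder traces honour the condition shape contracts", {
  b <- small_session()
  tr <- b$trials
  for (cond in c("IAE", "AE", "IA", "IE")) {
    ids <- tr$trial_id[tr$condition == cond]
    for (id in ids) {
      row <- tr[tr$trial_id == id, ]
      anchor <- if (!is.na(row$t_action_ms)) row$t_action_ms
      else row$t_decoder_intent_ms
      expect_equal(threshold_crossing(b$decoder[[id]]), anchor,
                   info = paste(cond, id))
    }
  }
  # IE falls after crossing while IA holds: compare mean value 800 ms post
  post_mean <- function(cond) {
    al <- align_decoder_traces(b, cond, c(600, 1000))
    mean(al$values)
  }
  expect_gt(post_mean("IA"), post_mean("IE") + 0.3)

  # ablation: with no pre-action lead the intended and NMES-evoked mean
  # profiles coincide before movement
  p0 <- generator_params(decoder_lead_ms = 0)
  t_grid <- seq(0, 8000, by = 100)
  prof_i <- intentchain:::decoder_mean_profile("IAE", 5000, t_grid, p0)
  prof_a <- intentchain:::decoder_mean_profile("AE", 5000, t_grid, p0)
  expect_equal(prof_i[t_grid < 5000], prof_a[t_grid < 5000])
  # with the default lead they diverge well before movement
  pd <- generator_params()
  prof_i2 <- intentchain:::decoder_mean_profile("IAE", 5000, t_grid, pd)
  expect_gt(max(abs(prof_i2 - prof_a)[t_grid < 4000]), 0.1)
})

test_that("LFP band envelopes follow the condition rules", {
  p <- generator_params(n_trials_per_condition = 8, with_spikes = FALSE,
                        with_decoder = FALSE)
  b <- generate_session(p, seed = 21L)
  delta_pre <- function(cond) {
    ids <- b$trials$trial_id[b$trials$condition == cond]
    mean(vapply(ids, function(id) {
      tr <- b$lfp[[id]]
      bp <- band_power_series(tr, freq_step = 1)
      rel <- trace_times(tr) - (tr$t0_ms + 2500)
      pre <- rel >= -900 & rel < -100
      base <- rel >= -2400 & rel < -1500
      mean(bp$power["delta", pre]) / mean(bp$power["delta", base])
    }, numeric(1)))
  }
  # sustained pre-movement delta power only when intention is present
  expect_gt(delta_pre("IAE"), 2)
  expect_lt(delta_pre("AE"), 1.6)
})
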