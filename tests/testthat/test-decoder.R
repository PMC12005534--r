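test_that("artifact blanking follows the 4-of-12 monitored-channel rule", {
  set.seed(21)
  raw <- matrix(rnorm(3000 * 14, 0, 20), 3000, 14)
  clean <- blank_artifacts(raw, monitor_channels = 1:12)
  expect_identical(clean$cleaned, raw)
  expect_identical(nrow(clean$intervals), 0L)

  # 600 uV on 5 monitored channels -> one 3.5 ms (105-sample) blank
  raw2 <- raw
  raw2[1500, 1:5] <- 600
  res <- blank_artifacts(raw2, monitor_channels = 1:12)
  expect_identical(nrow(res$intervals), 1L)
  expect_identical(res$intervals$end_sample - res$intervals$start_sample + 1L,
                   105L)
  expect_false(any(abs(res$cleaned) > 500))

  # only 3 monitored channels -> below the simultaneity rule, untouched
  raw3 <- raw
  raw3[1500, 1:3] <- 600
  res3 <- blank_artifacts(raw3, monitor_channels = 1:12)
  expect_identical(res3$cleaned, raw3)
  expect_error(blank_artifacts(raw[1:50, ]), "shorter")
})

test_that("MWP features isolate the multi-unit band", {
  expect_equal(dwt_level_band(30000, 3), c(1875, 3750))
  expect_equal(dwt_level_band(30000, 6), c(234.375, 468.75))

  # all-zero signal -> all-zero raw features
  z <- matrix(0, 6000, 2)
  f0 <- extract_mwp(z, normalize = "none")
  expect_true(all(f0$values == 0))

  # mid-band tone: detail level 4 (937.5-1875 Hz) dominates, in agreement
  # with a Butterworth filter-bank oracle
  fs <- 30000
  tt <- seq(0, 0.5, by = 1 / fs)
  x <- sin(2 * pi * 1300 * tt)
  det <- dwt_details(x, 8)
  energies <- vapply(det, function(d) mean(d^2), numeric(1))
  expect_identical(which.max(energies), 4L)
  bank <- vapply(1:6, function(l) {
    b <- dwt_level_band(fs, l) / (fs / 2)
    bf <- signal::butter(3, pmin(b[2], 0.999), type = "low")
    hf <- signal::butter(3, b[1], type = "high")
    y <- signal::filtfilt(bf, x)
    y <- signal::filtfilt(hf, y)
    mean(y^2)
  }, numeric(1))
  expect_identical(which.max(bank), 4L)

  # fs inconsistent with the 235-3750 Hz mapping -> remapped with warning
  expect_warning(extract_mwp(matrix(rnorm(8000), ncol = 1), fs = 20000),
                 "remapped")
})

test_that("classifier chain separates movement from rest and is deterministic", {
  set.seed(22)
  n_per <- 40; p <- 24
  mk <- function(mu) matrix(rnorm(n_per * p), n_per, p) +
    matrix(mu, n_per, p, byrow = TRUE)
  mu_hc <- c(rep(4, 6), rep(0, p - 6))
  mu_ho <- c(rep(0, p - 6), rep(4, 6))
  x <- rbind(mk(mu_hc), mk(mu_ho), mk(rep(0, p)))
  y <- rep(c("HC", "HO", "rest"), each = n_per)
  tr_idx <- c(1:20, 41:60, 81:100)
  model <- train_classifier(x[tr_idx, ], y[tr_idx], seed = 7L)
  expect_true(length(model$models$HC$feature_mask) >= 1)

  held <- setdiff(seq_len(3 * n_per), tr_idx)
  sc <- classify(model, x[held, ])
  pred_hc <- as.numeric(sc$values) > 0
  truth_hc <- y[held] == "HC"
  expect_gte(mean(pred_hc == truth_hc), 0.95)

  # identical bins give identical scores
  sc2 <- classify(model, x[held, ])
  expect_identical(sc$values, sc2$values)
  # rest-only stream stays below threshold
  rest_scores <- classify(model, mk(rep(0, p)))
  expect_lt(mean(as.numeric(rest_scores$values) > 0), 0.05)

  expect_error(train_classifier(x, rep("rest", nrow(x))), "movement")
  expect_error(classify(model, x[, 1:5]), "mismatch")
})

test_that("threshold crossing and objective intention timing behave as specified", {
  mk_trace <- function(v) continuous_trace("DECODER", 10, 0, v)
  expect_true(is.na(threshold_crossing(mk_trace(rep(-0.5, 20)))))
  v <- c(rep(-0.5, 7), 0.1, 0.3)
  expect_equal(threshold_crossing(mk_trace(v)), 700)

  expect_true(is.na(objective_intention_time(mk_trace(rep(-0.8, 10)),
                                             -0.8, 0.01)))
  v2 <- c(rep(-0.8, 5), rep(-0.6, 5))
  expect_equal(objective_intention_time(mk_trace(v2), -0.8, 0.02), 500)
  expect_error(objective_intention_time(mk_trace(v2), -0.8, 0), "variance")
})

test_that("surrogate crossing rate matches exhaustive enumeration", {
  # never-crossing trace -> 0 (values all negative)
  flat <- continuous_trace("DECODER", 10, 0, rep(-0.5, 100))
  expect_equal(surrogate_crossing_rate(list(flat), 1000, n_shifts = 50), 0)
  v <- rep(-0.5, 100)
  v[c(20, 55, 90)] <- 0.2 # three isolated crossings
  tr <- continuous_trace("DECODER", 10, 0, v)
  starts <- data.frame(trace = 1, start_ms = seq(0, 8900, by = 100))
  got <- surrogate_crossing_rate(list(tr), 1000, starts = starts)
  # direct enumeration with the same crossing rule
  tts <- trace_times(tr)
  brute <- mean(vapply(starts$start_ms, function(s) {
    w <- as.numeric(tr$values)[tts >= s & tts <= s + 1000]
    any(w[-1] >= 0 & w[-length(w)] < 0)
  }, logical(1)))
  expect_equal(got, brute)
  expect_gt(got, 0)
  expect_error(surrogate_crossing_rate(list(tr), 1e6, 10), "longer")
})

test_that("decoder AUC is an exact time-average with linear scaling", {
  mk_trace <- function(v) continuous_trace("DECODER", 10, 0, v)
  expect_equal(decoder_auc(mk_trace(rep(1, 41)), c(0, 4000)), 1)
  expect_equal(decoder_auc(mk_trace(rep(-1, 41)), c(0, 4000)), -1)
  set.seed(23)
  v <- runif(50, -1, 1)
  tr <- mk_trace(v)
  a <- decoder_auc(tr, c(500, 4200))
  tts <- trace_times(tr)
  keep <- tts >= 500 & tts <= 4200
  oracle <- pracma::trapz(tts[keep], v[keep]) / diff(range(tts[keep]))
  expect_equal(a, oracle, tolerance = 1e-12)
  for (s in c(0.5, -0.25, 1)) {
    expect_equal(decoder_auc(mk_trace(s * v), c(500, 4200)), s * a,
                 tolerance = 1e-12)
  }
  expect_error(decoder_auc(tr, c(10000, 11000)), "empty")
})

test_that("divergence detector finds constructed offsets and ignores identical groups", {
  set.seed(24)
  t_ms <- seq(-2000, 2000, by = 100)
  base <- function(n) matrix(rnorm(n * length(t_ms)), n)
  a <- base(25); b <- base(25)
  same <- timecourse_divergence(a, a + 0, t_ms)
  expect_true(is.na(same$earliest_ms))
  b_off <- b
  b_off[, t_ms >= -500] <- b_off[, t_ms >= -500] + 10
  res <- timecourse_divergence(a, b_off, t_ms)
  expect_lte(abs(res$earliest_ms - (-500)), 100)
  expect_error(timecourse_divergence(a, b[, 1:10], t_ms), "unequal")
})
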