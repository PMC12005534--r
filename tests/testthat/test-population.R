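test_that("condition PCA matches an independent eigen-decomposition", {
  set.seed(41)
  t_len <- 120; nch <- 8
  # rates confined to a 2-D subspace -> the retained pair explains it all
  basis <- matrix(rnorm(2 * nch), 2, nch)
  mats <- lapply(1:3, function(i) {
    w <- cbind(sin(seq_len(t_len) / (6 + i)), cos(seq_len(t_len) / (9 + i)))
    w %*% basis
  })
  names(mats) <- c("IAE", "AE", "IE")
  res <- condition_pca(mats)
  expect_equal(res$variance_explained, 1, tolerance = 1e-9)
  expect_equal(dim(res$trajectories$IAE), c(t_len, 2))

  # general rates: variance fraction equals the top-2 eigenvalue share
  mats2 <- lapply(mats, function(m) m + matrix(rnorm(length(m)), nrow(m)))
  res2 <- condition_pca(mats2)
  x <- do.call(rbind, mats2)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(res2$variance_explained, sum(ev[1:2]) / sum(ev),
               tolerance = 1e-9)
  expect_error(condition_pca(list(a = matrix(1, 10, 3))), "rank")
})

test_that("bootstrap distances vanish on zero rates and are rotation-invariant", {
  t_len <- 40; nch <- 6
  zero <- lapply(1:6, function(i) matrix(0, t_len, nch))
  d0 <- bootstrap_distance(zero, zero, seq_len(t_len), n_boot = 30)
  expect_true(all(d0$mean_distance == 0))
  expect_true(all(d0$ci_high == 0))

  set.seed(42)
  mk <- function(mu) lapply(1:8, function(i)
    matrix(rnorm(t_len * nch, mu), t_len, nch))
  a <- mk(0); b <- mk(0.8)
  d1 <- bootstrap_distance(a, b, seq_len(t_len), n_boot = 40, seed = 9L)
  rot <- qr.Q(qr(matrix(rnorm(nch^2), nch)))
  d2 <- bootstrap_distance(lapply(a, function(m) m %*% rot),
                           lapply(b, function(m) m %*% rot),
                           seq_len(t_len), n_boot = 40, seed = 9L)
  expect_equal(d1$mean_distance, d2$mean_distance, tolerance = 1e-6)
  expect_true(all(d1$ci_low <= d1$mean_distance + 1e-12))
  expect_true(all(d1$mean_distance <= d1$ci_high + 1e-12))
  expect_error(bootstrap_distance(a[1:2], b, seq_len(t_len)), ">= 5")
})

test_that("Morlet power maps localize oscillations in the right bands", {
  fs <- 200; n <- 20 * fs
  tt <- (seq_len(n) - 1) / fs
  mk_trace <- function(x) continuous_trace("LFP", fs, 0, x)
  # zero signal -> zero power
  p0 <- lfp_power_map(mk_trace(rep(0, n)))
  expect_true(all(p0$power == 0))
  # pure 10 Hz sine -> alpha row maximal
  p1 <- lfp_power_map(mk_trace(sin(2 * pi * 10 * tt)))
  peak_freq <- p1$freqs[which.max(rowMeans(p1$power))]
  expect_gte(peak_freq, 8); expect_lte(peak_freq, 13)

  # stationary two-tone signal: per-band peak powers agree with a
  # periodogram (short-time Fourier) oracle within 10%
  x <- 2 * sin(2 * pi * 2.5 * tt) + sin(2 * pi * 10 * tt)
  pm <- lfp_power_map(mk_trace(x))
  mid <- seq(round(n * 0.25), round(n * 0.75))
  pk <- function(lo, hi) {
    rows <- pm$freqs >= lo & pm$freqs <= hi
    max(rowMeans(pm$power[rows, mid, drop = FALSE]))
  }
  ratio <- pk(0.5, 4) / pk(8, 13)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0)
  band_int <- function(lo, hi) sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
  oracle <- band_int(0.5, 4) / band_int(8, 13)
  expect_equal(ratio, oracle, tolerance = 0.1)
  expect_error(morlet_power(rnorm(50), fs = 200, freqs = 0.5), "cycles")
})

test_that("band classifier separates injected power and stays at chance on null data", {
  set.seed(43)
  t_ms <- seq(-2500, 2499, by = 10)
  bands <- c("delta", "theta", "alpha", "beta")
  mk_trial <- function(delta_on) {
    base <- matrix(rexp(length(bands) * length(t_ms)), length(bands),
                   dimnames = list(bands, NULL))
    if (delta_on) base["delta", t_ms >= -1000] <-
        base["delta", t_ms >= -1000] + 6
    base
  }
  with_delta <- lapply(1:24, function(i) mk_trial(TRUE))
  res <- band_classification(with_delta, t_ms, step_ms = 200, seed = 3L)
  expect_lte(abs(res$first_significant_ms["delta"] - (-1000)), 200)

  null_trials <- lapply(1:24, function(i) mk_trial(FALSE))
  res0 <- band_classification(null_trials, t_ms, step_ms = 500, seed = 3L)
  # chance-level accuracy; false-positive steps at most the nominal level
  expect_lt(abs(mean(res0$curves$accuracy) - 0.5), 0.08)
  expect_lte(mean(res0$curves$p_value < 0.01), 0.05)
  expect_error(band_classification(null_trials[1:10], t_ms), ">= 20")
})
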