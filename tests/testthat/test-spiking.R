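test_that("binning and smoothing conserve spike count and match dense convolution", {
  z <- bin_and_smooth(numeric(), c(-500, 500))
  expect_true(all(z$rate_hz == 0))
  expect_length(z$t_ms, 1000)

  one <- bin_and_smooth(0, c(-500, 500))
  expect_equal(sum(one$rate_hz) / 1000, 1, tolerance = 1e-6)
  expect_equal(one$t_ms[which.max(one$rate_hz)], 0, tolerance = 1)

  set.seed(31)
  st <- sort(runif(200, -300, 300)) # interior: >= 4 kernel SD from the edges
  got <- bin_and_smooth(st, c(-500, 500), sd_ms = 50)
  # dense-convolution oracle
  kern <- exp(-0.5 * ((-200:200) / 50)^2)
  kern <- kern / sum(kern)
  edges <- seq(-700, 700, by = 1)
  cnt <- as.numeric(table(factor(floor(st) - (-700) + 1,
                                 levels = seq_len(1400))))
  dense <- as.numeric(stats::filter(cnt, kern, sides = 2)) * 1000
  idx <- match(got$t_ms, edges[-length(edges)])
  expect_lt(max(abs(got$rate_hz - dense[idx])), 1e-9)
  expect_equal(sum(got$rate_hz) / 1000, 200, tolerance = 1e-6)
})

test_that("alignment and averaging agree with a manual loop", {
  set.seed(32)
  spikes <- lapply(1:10, function(i) sort(runif(80, 0, 4000)))
  events <- runif(10, 1500, 2500)
  al <- aligned_rate_matrix(spikes, events, c(-1000, 1000))
  manual <- t(vapply(1:10, function(i)
    bin_and_smooth(spikes[[i]] - events[i], c(-1000, 1000))$rate_hz,
    numeric(2000)))
  expect_equal(al$values, manual)
  avg <- align_and_average(al)
  expect_equal(avg$mean_rate_hz, colMeans(manual))
  expect_equal(avg$sem_hz, apply(manual, 2, sd) / sqrt(10))
  one <- align_and_average(list(t_ms = al$t_ms,
                                values = al$values[1, , drop = FALSE]))
  expect_equal(one$mean_rate_hz, al$values[1, ])
  expect_true(all(one$sem_hz == 0))
})

test_that("evoked onset detects steps, skips flat traces and is translation-equivariant", {
  set.seed(33)
  t_ms <- -2000:1999
  noise <- rnorm(length(t_ms), 5, 0.05)
  flat <- data.frame(t_ms = t_ms, mean_rate_hz = noise)
  expect_true(is.na(evoked_onset(flat, c(-2000, -1500))))

  # injected step of 10x the baseline SD; after 50 ms kernel smoothing the
  # analytic step crosses the 5-SD threshold at half height, i.e., at the
  # true step time
  mk_step <- function(shift = 0) {
    base_sd <- 0.05
    step <- 10 * base_sd * pnorm((t_ms - shift) / 50)
    data.frame(t_ms = t_ms, mean_rate_hz = noise + step)
  }
  on0 <- evoked_onset(mk_step(0), c(-2000, -1500))
  expect_lte(abs(on0 - 0), 50) # within one smoothing SD
  # shifting trials and events shifts the onset equally
  stepped <- mk_step(0)
  shifted <- stepped
  shifted$t_ms <- shifted$t_ms + 137
  expect_equal(evoked_onset(shifted, c(-2000 + 137, -1500 + 137)),
               on0 + 137)
  expect_error(evoked_onset(data.frame(t_ms = t_ms, mean_rate_hz = 5),
                            c(-2000, -1500)), "variance")
})

test_that("zero-width perturbation leaves averages intact", {
  set.seed(34)
  spikes <- lapply(1:12, function(i) sort(runif(60, 0, 3000)))
  reports <- runif(12, 1200, 1800)
  res <- perturbation_robustness(spikes, reports, widths_ms = c(1e-9, 100),
                                 window_ms = c(-300, 300))
  expect_false(res$degraded[1])
  expect_error(perturbation_robustness(spikes, reports,
                                       widths_ms = c(100, 50)),
               "increasing")
  expect_error(perturbation_robustness(spikes[1:4], reports[1:4]), ">= 10")
})

test_that("stronger evoked responses reveal report jitter at smaller widths", {
  # the difference-from-original degradation rule gains power with response
  # amplitude, so the tolerance frontier shrinks as the response strengthens
  set.seed(35)
  t_gen <- seq(-1500, 1499, by = 1)
  widths <- seq(50, 600, by = 50)
  frontier <- vapply(c(3, 30), function(amp) {
    spikes <- lapply(1:30, function(i) {
      lam <- (5 + amp * pnorm(t_gen / 20)) / 1000
      t_gen[runif(length(t_gen)) < lam]
    })
    res <- perturbation_robustness(spikes, rep(0, 30), widths_ms = widths,
                                   window_ms = c(-400, 400), seed = 12L)
    if (any(res$degraded)) widths[which(res$degraded)[1]] else
      max(widths) + 50
  }, numeric(1))
  expect_lt(frontier[2], frontier[1])
})

test_that("spike-count correlations flag nothing when counts are constant", {
  spikes_by_unit <- list(lapply(1:10, function(i) c(-800, -400, -100)))
  reports <- rnorm(10, -600, 100)
  res <- sliding_spikecount_correlation(spikes_by_unit, reports)
  expect_identical(unname(res$n_sig), 0L)
  expect_true(is.na(res$r[1, 1]))
  expect_error(sliding_spikecount_correlation(spikes_by_unit, reports[1:2]),
               ">= 3")
})

test_that("intent-correlated generator units carry the injected correlation", {
  p <- generator_params()
  us <- data.frame(unit_id = "u", channel = 1L, is_sorted_unit = TRUE,
                   baseline_hz = 5, responsive = FALSE, f_I = 0,
                   t0_offset_ms = 0, alpha_ms = 20, transient_amp_hz = 0,
                   corr_beta = sqrt(5 * 0.25 / 0.75)) # target r = 0.5
  set.seed(36)
  n <- 50
  z <- rnorm(n)
  spikes <- vector("list", n)
  for (i in 1:n) {
    tr <- make_trial("IA", t_action = 5000, duration = 8000,
                     t_sub = 5000 - 597 + 200 * z[i], z = z[i])
    spikes[[i]] <- generate_spike_train(us, tr, p) - 5000
  }
  reports <- 200 * z # report co-varies with the latent time
  res <- sliding_spikecount_correlation(list(spikes), reports)
  expect_lt(abs(res$r[1, 1] - 0.5), 0.15)
})

test_that("sigmoid fits recover noiseless parameters exactly and rank by the grid", {
  t <- seq(-2000, 200, by = 1)
  y <- sigmoid_rate(t, f_I = 15, f_b = 5, t0_ms = -100, alpha_ms = 20)
  f <- fit_sigmoid(t, y)
  expect_equal(f$f_I, 15, tolerance = 1e-6)
  expect_equal(f$f_b, 5, tolerance = 1e-6)
  expect_equal(f$t0_ms, -100, tolerance = 1e-6)
  expect_equal(f$alpha_ms, 20, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_true(f$converged)

  # returned optimum dominates every grid start (oracle dominance)
  set.seed(37)
  yn <- y + rnorm(length(y), 0, 2)
  fn <- fit_sigmoid(t, yn)
  rss_fit <- sum((yn - sigmoid_rate(t, fn$f_I, fn$f_b, fn$t0_ms,
                                    fn$alpha_ms))^2)
  for (t0 in seq(-1900, 100, by = 200)) for (al in c(5, 20, 80)) {
    s <- 1 / (1 + exp(-(t - t0) / al))
    cf <- coef(lm(yn ~ s))
    rss_grid <- sum((yn - cf[1] - cf[2] * s)^2)
    expect_lte(rss_fit, rss_grid + 1e-6)
  }
})

test_that("fit retention applies the strict r-squared rule", {
  fits <- data.frame(f_I = 1, f_b = 1, t0_ms = c(-50, -100, -150),
                     alpha_ms = c(10, 20, 30),
                     r_squared = c(0.4, 0.5, 0.6), converged = TRUE)
  s <- summarize_fits(fits, r2_threshold = 0.5)
  expect_identical(s$n_retained, 1L)
  expect_equal(s$retained$t0_ms, -150)
  s0 <- summarize_fits(transform(fits, r_squared = 0))
  expect_identical(s0$n_retained, 0L)
  expect_true(is.na(s0$mean_t0_ms))
})
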