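#' PCA of condition-averaged population rates
#'
#' Fits a principal component analysis on the time-concatenated
#' condition-average firing rates (channels as variables) and projects each
#' condition's average trajectory onto the first two components.
#'
#' @param rate_mats Named list (one element per condition) of matrices
#'   (time x channels) on a common grid.
#' @return List: `trajectories` (named list of time x 2 score matrices),
#'   `variance_explained` (fraction for the retained pair), `rotation`,
#'   `center`, `sdev`.
#' @export
condition_pca <- function(rate_mats) {
  stopifnot(is.list(rate_mats), length(rate_mats) >= 1)
  nch <- unique(vapply(rate_mats, ncol, integer(1)))
  if (length(nch) != 1) stop("conditions disagree on channel count")
  x <- do.call(rbind, rate_mats)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-12) < 2) stop("population rates have rank < 2")
  ve <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  idx <- rep(names(rate_mats), vapply(rate_mats, nrow, integer(1)))
  traj <- lapply(stats::setNames(names(rate_mats), names(rate_mats)),
                 function(nm) scores[idx == nm, , drop = FALSE])
  list(trajectories = traj, variance_explained = ve,
       rotation = pc$rotation[, 1:2, drop = FALSE], center = pc$center,
       sdev = pc$sdev)
}

#' Bootstrap distance between two latent trajectories
#'
#' For each bootstrap draw, trials are resampled with replacement within
#' each condition, condition means recomputed, PCA refit on the
#' concatenated means, and the 2-D Euclidean distance between the two
#' projected trajectories measured per time bin; percentile 95% confidence
#' bounds are returned.
#'
#' @param trials_a,trials_b Lists of per-trial matrices (time x channels) on
#'   a common grid.
#' @param t_ms Time grid (ms).
#' @param n_boot Bootstrap draws (default 1,000).
#' @param seed RNG seed.
#' @return Data frame `(t_ms, mean_distance, ci_low, ci_high, n_boot)`.
#' @export
bootstrap_distance <- function(trials_a, trials_b, t_ms, n_boot = 1000,
                               seed = 1L) {
  if (length(trials_a) < 5 || length(trials_b) < 5)
    stop("need >= 5 trials per condition")
  nt <- length(t_ms)
  avg <- function(lst, idx) Reduce(`+`, lst[idx]) / length(idx)
  dist_one <- function(ma, mb) {
    x <- rbind(ma, mb)
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    if (sum(xc^2) < 1e-24) return(rep(0, nt))
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(2L, sum(pc$sdev > 1e-12))
    sa <- pc$x[seq_len(nt), seq_len(k), drop = FALSE]
    sb <- pc$x[nt + seq_len(nt), seq_len(k), drop = FALSE]
    sqrt(rowSums((sa - sb)^2))
  }
  boot <- with_seed(seed, {
    out <- matrix(0, n_boot, nt)
    for (b in seq_len(n_boot)) {
      ia <- sample(length(trials_a), replace = TRUE)
      ib <- sample(length(trials_b), replace = TRUE)
      out[b, ] <- dist_one(avg(trials_a, ia), avg(trials_b, ib))
    }
    out
  })
  data.frame(t_ms = t_ms, mean_distance = colMeans(boot),
             ci_low = apply(boot, 2, stats::quantile, 0.025),
             ci_high = apply(boot, 2, stats::quantile, 0.975),
             n_boot = n_boot)
}

#' Canonical LFP frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz.
#' @return Named list of `c(low, high)` pairs.
#' @export
lfp_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Time-frequency power map of an LFP trace
#'
#' Morlet continuous-wavelet power, optionally normalized per frequency by
#' the mean power in a baseline window.
#'
#' @param trace A `continuous_trace` of kind LFP (or any numeric vector via
#'   `x`/`fs`/`t0_ms`).
#' @param freqs Frequencies (Hz), default 0.5-30 in 0.5 Hz steps.
#' @param baseline_window_ms Optional `c(from, to)` in trace time.
#' @return List: `t_ms`, `freqs`, `power` (frequencies x samples).
#' @export
lfp_power_map <- function(trace, freqs = seq(0.5, 30, by = 0.5),
                          baseline_window_ms = NULL) {
  x <- as.numeric(trace$values)
  tts <- trace_times(trace)
  bidx <- if (!is.null(baseline_window_ms))
    which(tts >= baseline_window_ms[1] & tts < baseline_window_ms[2])
  else NULL
  mp <- morlet_power(x, trace$fs_hz, freqs, baseline_idx = bidx)
  list(t_ms = tts, freqs = mp$freqs, power = mp$power)
}

#' Band-power time series per trial
#'
#' @param trace An LFP `continuous_trace`.
#' @param bands Named list of band edges (default [lfp_bands()]).
#' @param freq_step Frequency resolution of the underlying Morlet map.
#' @return List: `t_ms`, `power` (bands x samples), `bands`.
#' @export
band_power_series <- function(trace, bands = lfp_bands(), freq_step = 0.5) {
  freqs <- seq(min(vapply(bands, `[`, numeric(1), 1)),
               max(vapply(bands, `[`, numeric(1), 2)), by = freq_step)
  mp <- lfp_power_map(trace, freqs)
  pw <- t(vapply(bands, function(b) {
    rows <- mp$freqs >= b[1] & mp$freqs <= b[2]
    colMeans(mp$power[rows, , drop = FALSE])
  }, numeric(length(mp$t_ms))))
  rownames(pw) <- names(bands)
  list(t_ms = mp$t_ms, power = pw, bands = bands)
}

#' Baseline-vs-induced band-power classification
#'
#' Per band and 100 ms test step, a cross-validated SVM separates each
#' trial's baseline power (default window -2,200 to -2,000 ms) from its
#' power at the test step; accuracy significantly above chance (binomial
#' test) marks the step as separable, and the earliest such step is
#' reported per band.
#'
#' @param band_power_by_trial List over trials of matrices (bands x time)
#'   from [band_power_series()], on a common anchor-relative grid.
#' @param t_ms Anchor-relative sample times of those matrices.
#' @param baseline_window `c(from, to)` ms (default `c(-2200, -2000)`).
#' @param test_range `c(from, to)` ms (default `c(-2000, 2000)`).
#' @param step_ms Test-step spacing (default 100).
#' @param folds Cross-validation folds (default 10).
#' @param p_crit Binomial significance level (default 0.01).
#' @param seed RNG seed for fold assignment.
#' @return List: `curves` (data frame band x step with accuracy and p) and
#'   `first_significant_ms` (named per band).
#' @export
band_classification <- function(band_power_by_trial, t_ms,
                                baseline_window = c(-2200, -2000),
                                test_range = c(-2000, 2000), step_ms = 100,
                                folds = 10, p_crit = 0.01, seed = 1L) {
  n_trials <- length(band_power_by_trial)
  if (n_trials < 20) stop("need >= 20 trials")
  if (n_trials / folds < 2) stop("fold size < 2")
  bands <- rownames(band_power_by_trial[[1]])
  steps <- seq(test_range[1], test_range[2], by = step_ms)
  base_idx <- which(t_ms >= baseline_window[1] & t_ms < baseline_window[2])
  if (!length(base_idx)) stop("baseline window outside the grid")
  # test windows share the baseline's width so that baseline and induced
  # features are exchangeable under the null (unequal averaging windows
  # would differ in variance, which a classifier can exploit)
  test_width <- diff(baseline_window)
  win_mean <- function(mat, idx) rowMeans(mat[, idx, drop = FALSE])
  base_feat <- vapply(band_power_by_trial, win_mean, numeric(length(bands)),
                      idx = base_idx)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds),
                                        length.out = 2 * n_trials)))
  rows <- list()
  first_sig <- stats::setNames(rep(NA_real_, length(bands)), bands)
  for (bi in seq_along(bands)) {
    for (si in seq_along(steps)) {
      idx <- which(t_ms >= steps[si] & t_ms < steps[si] + test_width)
      if (!length(idx)) next
      test_feat <- vapply(band_power_by_trial, function(m)
        mean(m[bi, idx]), numeric(1))
      x <- matrix(c(base_feat[bi, ], test_feat), ncol = 1)
      yy <- factor(rep(c("base", "test"), each = n_trials))
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_id != f; te <- fold_id == f
        if (length(unique(yy[tr])) < 2) next
        fit <- e1071::svm(x[tr, , drop = FALSE], yy[tr], kernel = "radial")
        pred <- stats::predict(fit, x[te, , drop = FALSE])
        correct <- correct + sum(pred == yy[te])
      }
      acc <- correct / (2 * n_trials)
      p <- stats::binom.test(correct, 2 * n_trials, 0.5,
                             alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        band = bands[bi], t_ms = steps[si], accuracy = acc, p_value = p)
      if (p < p_crit && is.na(first_sig[bands[bi]]))
        first_sig[bands[bi]] <- steps[si]
    }
  }
  list(curves = do.call(rbind, rows), first_significant_ms = first_sig)
}

#' Decimate a wideband signal to an LFP rate
#'
#' Anti-alias low-pass (8th-order Butterworth at 0.4 x target rate, applied
#' forward-backward) followed by subsampling.
#'
#' @param x Numeric signal.
#' @param fs_from,fs_to Source and target sampling rates (Hz);
#'   `fs_from / fs_to` must be an integer.
#' @return Decimated numeric vector.
#' @export
decimate_lfp <- function(x, fs_from, fs_to = 1000) {
  stopifnot(fs_from %% fs_to == 0)
  q <- fs_from / fs_to
  if (q == 1) return(x)
  bf <- signal::butter(4, 0.8 / q, type = "low")
  y <- signal::filtfilt(bf, x)
  y[seq(1, length(y), by = q)]
}
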