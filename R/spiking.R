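#' Bin and smooth a spike train into a firing-rate trace
#'
#' Spikes are binned at 1 ms and convolved with a Gaussian kernel (default
#' SD 50 ms, truncated at +/- 4 SD, unit area), scaled to Hz. The kernel's
#' unit area makes smoothing conserve spike count: the integral of the rate
#' equals the number of interior spikes.
#'
#' @param spike_times_ms Spike times (ms), any order.
#' @param window_ms `c(from, to)`: output time range (bin starts).
#' @param bin_ms Bin width (default 1 ms).
#' @param sd_ms Gaussian kernel SD (default 50 ms).
#' @return List `(t_ms, rate_hz)` on the 1 ms grid.
#' @export
bin_and_smooth <- function(spike_times_ms, window_ms, bin_ms = 1,
                           sd_ms = 50) {
  pad <- ceiling(4 * sd_ms / bin_ms) * bin_ms
  edges <- seq(window_ms[1] - pad, window_ms[2] + pad, by = bin_ms)
  counts <- bin_counts(spike_times_ms, c(edges, edges[length(edges)] + bin_ms))
  kern <- gaussian_kernel_ms(sd_ms, bin_ms)
  sm <- conv_same(counts, kern) * 1000 / bin_ms
  keep <- edges >= window_ms[1] & edges < window_ms[2]
  list(t_ms = edges[keep], rate_hz = sm[keep])
}

#' Event-aligned single-trial rate matrix
#'
#' Computes each trial's smoothed rate on a grid aligned to that trial's
#' event (0 = event); trials whose data do not cover the window are dropped
#' with a message.
#'
#' @param spikes_by_trial List of spike-time vectors (trial-relative ms).
#' @param event_times_ms Alignment event per trial (same length).
#' @param window_ms `c(from, to)` around the event.
#' @param durations_ms Optional trial durations for coverage checking.
#' @param bin_ms,sd_ms Binning and smoothing parameters.
#' @return List `(t_ms, values)`; `values` is trials x bins.
#' @export
aligned_rate_matrix <- function(spikes_by_trial, event_times_ms, window_ms,
                                durations_ms = NULL, bin_ms = 1, sd_ms = 50) {
  stopifnot(length(spikes_by_trial) == length(event_times_ms))
  rows <- list()
  t_out <- NULL
  for (i in seq_along(spikes_by_trial)) {
    ev <- event_times_ms[i]
    if (is.na(ev)) next
    if (!is.null(durations_ms) &&
        (ev + window_ms[1] < 0 || ev + window_ms[2] > durations_ms[i])) {
      message(sprintf("trial %d dropped: window not covered", i))
      next
    }
    sm <- bin_and_smooth(spikes_by_trial[[i]] - ev, window_ms,
                         bin_ms = bin_ms, sd_ms = sd_ms)
    t_out <- sm$t_ms
    rows[[length(rows) + 1L]] <- sm$rate_hz
  }
  if (!length(rows)) stop("no trial covers the alignment window")
  list(t_ms = t_out, values = do.call(rbind, rows))
}

#' Trial-averaged multi-unit activity
#'
#' @param aligned A list from [aligned_rate_matrix()] (or any
#'   `(t_ms, values)` pair with trials in rows).
#' @return Data frame `(t_ms, mean_rate_hz, sem_hz, n_trials)`.
#' @export
align_and_average <- function(aligned) {
  v <- as.matrix(aligned$values)
  n <- nrow(v)
  data.frame(t_ms = aligned$t_ms,
             mean_rate_hz = colMeans(v),
             sem_hz = if (n > 1) apply(v, 2, stats::sd) / sqrt(n) else 0,
             n_trials = n)
}

#' Evoked-response onset (k-SD rule)
#'
#' Noise is the SD of the trial-averaged trace over the baseline window;
#' the onset is the first bin where the average exceeds the baseline mean by
#' `k` noise SDs and stays above for at least `sustain_ms` (suppressing
#' single-bin noise).
#'
#' @param mua Data frame from [align_and_average()].
#' @param baseline_window `c(from, to)` (ms), preceding the search region.
#' @param k SD multiple (default 5).
#' @param sustain_ms Required supra-threshold run length (default 10 ms).
#' @param search_window Optional `c(from, to)` restriction of the search.
#' @return Onset time (ms) or `NA`.
#' @export
evoked_onset <- function(mua, baseline_window, k = 5, sustain_ms = 10,
                         search_window = NULL) {
  base <- mua$mean_rate_hz[mua$t_ms >= baseline_window[1] &
                             mua$t_ms < baseline_window[2]]
  if (length(base) < 2) stop("baseline window too short")
  noise <- stats::sd(base)
  if (noise == 0) stop("zero baseline variance")
  thr <- mean(base) + k * noise
  t <- mua$t_ms
  v <- mua$mean_rate_hz
  if (!is.null(search_window)) {
    keep <- t >= search_window[1] & t < search_window[2]
  } else {
    keep <- t >= baseline_window[2]
  }
  t <- t[keep]; v <- v[keep]
  above <- v > thr
  if (!any(above)) return(NA_real_)
  bin <- if (length(t) > 1) t[2] - t[1] else 1
  need <- max(1L, round(sustain_ms / bin))
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= need)
  if (!length(ok)) return(NA_real_)
  t[starts[ok[1]]]
}

#' Robustness of evoked responses to report jitter
#'
#' Re-aligns trials to jittered reports (uniform on `[-w, +w]`) for a
#' ladder of widths and tests, per 1 ms bin, whether the jittered ensemble
#' differs from the original (unpaired t). A response counts as degraded at
#' width `w` once at least `degrade_bins` bins differ at `p < p_crit`.
#'
#' @param spikes_by_trial List of spike-time vectors (trial-relative ms).
#' @param report_times_ms Report-aligned event per trial.
#' @param widths_ms Increasing jitter half-widths (default 10..1,000 by 10).
#' @param window_ms Alignment window (default `c(-500, 500)`).
#' @param degrade_bins,p_crit Degradation rule (defaults 10 bins at 0.01).
#' @param sd_ms Smoothing SD.
#' @param seed RNG seed for the jitter draws.
#' @return List: `widths_ms`, `degraded` (logical), `n_sig_bins`,
#'   `max_tolerated_width_ms`.
#' @export
perturbation_robustness <- function(spikes_by_trial, report_times_ms,
                                    widths_ms = seq(10, 1000, by = 10),
                                    window_ms = c(-500, 500),
                                    degrade_bins = 10, p_crit = 0.01,
                                    sd_ms = 50, seed = 1L) {
  if (any(diff(widths_ms) <= 0)) stop("widths must be strictly increasing")
  if (length(spikes_by_trial) < 10) stop("need >= 10 trials")
  orig <- aligned_rate_matrix(spikes_by_trial, report_times_ms, window_ms,
                              sd_ms = sd_ms)
  n_sig <- integer(length(widths_ms))
  with_seed(seed, {
    for (wi in seq_along(widths_ms)) {
      w <- widths_ms[wi]
      jit <- stats::runif(length(report_times_ms), -w, w)
      pert <- aligned_rate_matrix(spikes_by_trial, report_times_ms + jit,
                                  window_ms, sd_ms = sd_ms)
      p <- welch_p_columns(orig$values, pert$values)
      n_sig[wi] <- sum(p < p_crit, na.rm = TRUE)
    }
  })
  degraded <- n_sig >= degrade_bins
  list(widths_ms = widths_ms, degraded = degraded, n_sig_bins = n_sig,
       max_tolerated_width_ms = if (any(!degraded)) max(widths_ms[!degraded])
       else 0)
}

#' Sliding spike-count correlation with report times
#'
#' For each unit and window center, the Pearson correlation across trials
#' between the spike count in a window (default 1,000 ms) and the subjective
#' report time. The default single center at -500 ms covers the second
#' preceding the action. Windows with zero count variance are undefined and
#' marked not significant.
#'
#' @param spikes_by_unit List over units; each element a list over trials of
#'   event-aligned spike times (0 = action).
#' @param report_times_ms Report time per trial (event-relative ms).
#' @param centers_ms Window centers (default -500).
#' @param window_ms Window width (default 1,000).
#' @param p_crit Per-unit significance level (default 0.05).
#' @return List: `r` and `p` (units x centers), `n_sig` per center,
#'   `centers_ms`.
#' @export
sliding_spikecount_correlation <- function(spikes_by_unit, report_times_ms,
                                           centers_ms = -500,
                                           window_ms = 1000,
                                           p_crit = 0.05) {
  n_trials <- length(report_times_ms)
  if (n_trials < 3) stop("need >= 3 trials")
  n_units <- length(spikes_by_unit)
  r <- matrix(NA_real_, n_units, length(centers_ms))
  p <- matrix(1, n_units, length(centers_ms))
  half <- window_ms / 2
  for (u in seq_len(n_units)) {
    st <- spikes_by_unit[[u]]
    stopifnot(length(st) == n_trials)
    counts <- matrix(0L, n_trials, length(centers_ms))
    for (i in seq_len(n_trials)) {
      s <- sort(st[[i]])
      counts[i, ] <- findInterval(centers_ms + half, s) -
        findInterval(centers_ms - half, s)
    }
    for (ci in seq_along(centers_ms)) {
      x <- counts[, ci]
      if (stats::sd(x) == 0 || stats::sd(report_times_ms) == 0) next
      rr <- stats::cor(x, report_times_ms)
      tt <- rr * sqrt((n_trials - 2) / max(1 - rr^2, 1e-12))
      r[u, ci] <- rr
      p[u, ci] <- 2 * stats::pt(-abs(tt), n_trials - 2)
    }
  }
  list(r = r, p = p, centers_ms = centers_ms,
       n_sig = as.integer(colSums(p < p_crit, na.rm = TRUE)))
}
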