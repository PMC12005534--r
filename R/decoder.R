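#' Blank stimulation artifacts in raw data
#'
#' NMES artifacts are detected as moments where the absolute signal exceeds
#' `threshold_uv` simultaneously on at least `min_channels` of 12 monitor
#' channels (drawn once per session from `seed`); each detection is blanked
#' over `blank_ms` around the artifact on all channels by linear
#' interpolation across the gap.
#'
#' @param raw Matrix (samples x channels), in uV; needs >= 12 channels.
#' @param fs Sampling rate (Hz).
#' @param threshold_uv Detection threshold (default 500).
#' @param min_channels Simultaneity requirement (default 4).
#' @param blank_ms Blanked duration per artifact (default 3.5 ms).
#' @param monitor_channels Optional explicit monitor-channel indices;
#'   otherwise 12 channels are sampled using `seed`.
#' @param seed Session seed for the monitor-channel draw.
#' @return List: `cleaned` (matrix), `intervals` (data frame of blanked
#'   sample ranges, possibly empty).
#' @export
blank_artifacts <- function(raw, fs = 30000, threshold_uv = 500,
                            min_channels = 4, blank_ms = 3.5,
                            monitor_channels = NULL, seed = 1L) {
  raw <- as.matrix(raw)
  n <- nrow(raw)
  half <- round(blank_ms / 2 * fs / 1000)
  win <- 2L * half + 1L
  if (n < win) stop("snippet shorter than the blank window")
  if (ncol(raw) < 12) stop("artifact blanking needs >= 12 channels")
  if (is.null(monitor_channels)) {
    monitor_channels <- with_seed(seed, sample(ncol(raw), 12))
  }
  hits <- rowSums(abs(raw[, monitor_channels, drop = FALSE]) >
                    threshold_uv) >= min_channels
  idx <- which(hits)
  cleaned <- raw
  intervals <- list()
  while (length(idx)) {
    center <- idx[1]
    lo <- max(1L, center - half)
    hi <- min(n, lo + win - 1L)
    lo <- max(1L, hi - win + 1L)
    for (ch in seq_len(ncol(cleaned))) {
      a <- if (lo > 1) cleaned[lo - 1, ch] else cleaned[hi + 1, ch]
      b <- if (hi < n) cleaned[hi + 1, ch] else cleaned[lo - 1, ch]
      cleaned[lo:hi, ch] <- a + (b - a) * seq_len(hi - lo + 1) / (hi - lo + 2)
    }
    intervals[[length(intervals) + 1L]] <-
      data.frame(start_sample = as.integer(lo), end_sample = as.integer(hi),
                 t_ms = (center - 1) / fs * 1000)
    idx <- idx[idx > hi]
  }
  list(cleaned = cleaned,
       intervals = if (length(intervals)) do.call(rbind, intervals)
       else data.frame(start_sample = integer(), end_sample = integer(),
                       t_ms = numeric()))
}

#' Train the movement classifier
#'
#' One-vs-rest models per attempted movement (hand close `HC`, hand open
#' `HO`): an L1-penalized logistic fit ranks the mean-wavelet-power features
#' and zeroes out the least valuable ones (sparsity optimization), then an
#' RBF-kernel SVM is trained on the retained features. Decision values are
#' scaled by the largest training magnitude so scores live in `[-1, 1]`
#' with rest negative.
#'
#' @param features Matrix (bins x features), e.g. `extract_mwp()$values`.
#' @param labels Character/factor per bin: `"HC"`, `"HO"` or `"rest"`.
#' @param sparsity_level Fraction of features to zero out (default 0.5).
#' @param seed Seed for the (seeded) fitting stages.
#' @return Object of class `movement_classifier` with one model per
#'   movement present, each holding `feature_mask`, the SVM fit, the
#'   orientation sign and the calibration scale.
#' @export
train_classifier <- function(features, labels, sparsity_level = 0.5,
                             seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  movements <- intersect(c("HC", "HO"), unique(labels))
  if (!length(movements) || !any(labels == "rest"))
    stop("training needs at least one movement class and rest")
  if (any(table(labels) < 2)) stop("each class needs >= 2 examples")
  models <- list()
  for (m in movements) {
    y <- as.integer(labels == m)
    keep_rows <- labels %in% c(m, "rest")
    xm <- features[keep_rows, , drop = FALSE]
    ym <- y[keep_rows]
    n_keep <- max(1L, ceiling(ncol(features) * (1 - sparsity_level)))
    mask <- with_seed(child_seed(seed, match(m, movements)), {
      if (ncol(xm) >= 2) {
        fit <- glmnet::glmnet(xm, ym, family = "binomial", nlambda = 60)
        nz <- fit$df
        li <- which(nz >= n_keep)[1]
        if (is.na(li)) li <- length(nz)
        beta <- abs(as.numeric(fit$beta[, li]))
        order(beta, decreasing = TRUE)[seq_len(min(n_keep, sum(beta > 0) +
                                                     (sum(beta > 0) == 0)))]
      } else 1L
    })
    mask <- sort(unique(mask))
    svm_fit <- with_seed(child_seed(seed, 10L + match(m, movements)),
      e1071::svm(x = xm[, mask, drop = FALSE], y = factor(ym),
                 kernel = "radial", scale = length(mask) > 1))
    dv <- attr(stats::predict(svm_fit, xm[, mask, drop = FALSE],
                              decision.values = TRUE), "decision.values")[, 1]
    orient <- if (mean(dv[ym == 1]) >= mean(dv[ym == 0])) 1 else -1
    models[[m]] <- list(feature_mask = mask, svm = svm_fit,
                        orient = orient, scale = max(abs(dv), 1e-12),
                        n_features = ncol(features))
  }
  structure(list(models = models), class = "movement_classifier")
}

#' Score feature bins with a trained classifier
#'
#' @param model A `movement_classifier` from [train_classifier()].
#' @param features Matrix (bins x features) with the training feature count.
#' @param movement Which one-vs-rest model to apply (default `"HC"`).
#' @param t0_ms Time of the first bin.
#' @param bin_ms Bin width (default 100).
#' @return A `continuous_trace` of kind `"DECODER"`: one score per bin,
#'   clipped to `[-1, 1]`.
#' @export
classify <- function(model, features, movement = "HC", t0_ms = 0,
                     bin_ms = 100) {
  stopifnot(inherits(model, "movement_classifier"))
  m <- model$models[[movement]]
  if (is.null(m)) stop(sprintf("no model for movement '%s'", movement))
  features <- as.matrix(features)
  if (ncol(features) != m$n_features)
    stop(sprintf("feature dimensionality mismatch: got %d, expected %d",
                 ncol(features), m$n_features))
  x <- features[, m$feature_mask, drop = FALSE]
  dv <- attr(stats::predict(m$svm, x, decision.values = TRUE),
             "decision.values")[, 1]
  score <- pmin(1, pmax(-1, m$orient * dv / m$scale))
  continuous_trace("DECODER", 1000 / bin_ms, t0_ms, as.numeric(score))
}

#' Decoder threshold crossing (movement trigger)
#'
#' @param trace A decoder `continuous_trace`.
#' @return Start time (ms) of the first bin with score >= 0 that follows a
#'   sub-zero bin, or `NA` if the trace never crosses.
#' @export
threshold_crossing <- function(trace) {
  v <- as.numeric(trace$values)
  if (length(v) < 2) return(NA_real_)
  idx <- which(v[-1] >= 0 & v[-length(v)] < 0)
  if (!length(idx)) return(NA_real_)
  trace_times(trace)[idx[1] + 1L]
}

#' Objective intention time (5-SD rule)
#'
#' The first bin in which the decoder exceeds the rest-period noise mean by
#' `k` noise SDs — a more liberal criterion than the movement threshold,
#' taken as the within-trial "objective" timing of decodable intention.
#'
#' @param trace A decoder `continuous_trace`.
#' @param noise_mean,noise_sd Rest-period noise statistics (e.g., from
#'   [decoder_rest_noise()]).
#' @param k SD multiple (default 5).
#' @return Bin start time (ms), or `NA` if never exceeded.
#' @export
objective_intention_time <- function(trace, noise_mean, noise_sd, k = 5) {
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("zero-variance noise estimate")
  v <- as.numeric(trace$values)
  idx <- which(v > noise_mean + k * noise_sd)
  if (!length(idx)) return(NA_real_)
  trace_times(trace)[idx[1]]
}

#' Rest-period decoder noise statistics
#'
#' Pools decoder bins well before each trial's anchor event (the within-
#' trial rest segments) and returns their mean and SD; requires at least
#' 5 s of pooled rest.
#'
#' @param bundle A [session_bundle()].
#' @param margin_ms Bins earlier than `anchor - margin_ms` count as rest.
#' @return List `(mean, sd, n_bins)`.
#' @export
decoder_rest_noise <- function(bundle, margin_ms = 2500) {
  pooled <- numeric()
  for (id in names(bundle$decoder)) {
    tr <- bundle$trials[bundle$trials$trial_id == id, ]
    anchor <- trial_anchor_ms(tr)
    if (is.na(anchor)) next
    trace <- bundle$decoder[[id]]
    tts <- trace_times(trace)
    pooled <- c(pooled, as.numeric(trace$values)[tts < anchor - margin_ms])
  }
  if (length(pooled) * 100 < 5000)
    stop("fewer than 5 s of pooled rest bins")
  list(mean = mean(pooled), sd = stats::sd(pooled), n_bins = length(pooled))
}

#' Surrogate crossing rate
#'
#' Fraction of randomly placed surrogate request windows that contain at
#' least one decoder zero-crossing — the rate of spontaneous (unrequested)
#' movement triggers.
#'
#' @param traces List of decoder `continuous_trace` objects.
#' @param window_ms Surrogate window duration (ms).
#' @param n_shifts Number of random placements.
#' @param seed RNG seed.
#' @param starts Optional data frame `(trace, start_ms)` of explicit
#'   placements (overrides random shifting; used by exhaustive tests).
#' @return Fraction in `[0, 1]`.
#' @export
surrogate_crossing_rate <- function(traces, window_ms, n_shifts = 1000,
                                    seed = 1L, starts = NULL) {
  if (is.null(starts) && n_shifts < 1) stop("n_shifts must be >= 1")
  durs <- vapply(traces, function(tr) {
    tts <- trace_times(tr)
    max(tts) - min(tts)
  }, numeric(1))
  if (any(window_ms > durs))
    stop("surrogate window longer than a session trace")
  if (is.null(starts)) {
    starts <- with_seed(seed, {
      ti <- sample(length(traces), n_shifts, replace = TRUE)
      data.frame(trace = ti,
                 start_ms = stats::runif(n_shifts, 0, durs[ti] - window_ms))
    })
  }
  hit <- logical(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    tr <- traces[[starts$trace[i]]]
    tts <- trace_times(tr)
    w0 <- min(tts) + starts$start_ms[i]
    inwin <- tts >= w0 & tts <= w0 + window_ms
    v <- as.numeric(tr$values)[inwin]
    hit[i] <- length(v) >= 2 && any(v[-1] >= 0 & v[-length(v)] < 0)
  }
  mean(hit)
}

#' Area under the decoder curve
#'
#' Time-average of the trace over a window: trapezoidal integral divided by
#' the spanned duration. Bounded in `[-1, 1]` because the trace is.
#'
#' @param trace A decoder `continuous_trace`.
#' @param window `c(start_ms, end_ms)`, within the trace.
#' @return Scalar in `[-1, 1]`.
#' @export
decoder_auc <- function(trace, window) {
  tts <- trace_times(trace)
  keep <- tts >= window[1] & tts <= window[2]
  if (sum(keep) < 2) stop("empty AUC window")
  t <- tts[keep]
  v <- as.numeric(trace$values)[keep]
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (t[length(t)] - t[1])
}

#' Earliest significant divergence between two trace ensembles
#'
#' Per-bin unpaired (Welch) t-tests, Bonferroni-corrected over bins; returns
#' the earliest bin whose corrected p falls below `alpha`.
#'
#' @param traces_a,traces_b Matrices (trials x bins) on a common time grid.
#' @param t_ms Bin times (shared by both groups).
#' @param alpha Corrected significance level (default 0.01).
#' @return List: `earliest_ms` (or `NA`), `t_ms`, `p` (raw), `p_adj`.
#' @export
timecourse_divergence <- function(traces_a, traces_b, t_ms, alpha = 0.01) {
  traces_a <- as.matrix(traces_a); traces_b <- as.matrix(traces_b)
  if (ncol(traces_a) != ncol(traces_b) || ncol(traces_a) != length(t_ms))
    stop("unequal time grids")
  if (nrow(traces_a) < 2 || nrow(traces_b) < 2)
    stop("need >= 2 trials per group")
  p <- welch_p_columns(traces_a, traces_b)
  p_adj <- pmin(1, p * length(p))
  sig <- which(p_adj < alpha)
  list(earliest_ms = if (length(sig)) t_ms[sig[1]] else NA_real_,
       t_ms = t_ms, p = p, p_adj = p_adj)
}

#' Anchor-aligned decoder traces for a set of trials
#'
#' @param bundle A [session_bundle()].
#' @param conditions Conditions to include.
#' @param window_ms Alignment window around the anchor, `c(from, to)`.
#' @return List: `t_ms` (bin times relative to the anchor) and `values`
#'   (matrix trials x bins); trials not covering the window are dropped.
#' @export
align_decoder_traces <- function(bundle, conditions,
                                 window_ms = c(-2000, 2000)) {
  bin <- bundle$config$decoder_bin_ms
  grid <- seq(window_ms[1], window_ms[2], by = bin)
  rows <- list()
  ids <- bundle$trials$trial_id[bundle$trials$condition %in% conditions]
  for (id in intersect(ids, names(bundle$decoder))) {
    tr <- bundle$trials[bundle$trials$trial_id == id, ]
    anchor <- trial_anchor_ms(tr)
    if (is.na(anchor)) next
    trace <- bundle$decoder[[id]]
    tts <- trace_times(trace) - anchor
    if (min(tts) > grid[1] || max(tts) < grid[length(grid)]) next
    rows[[id]] <- stats::approx(tts, as.numeric(trace$values), xout = grid,
                                method = "constant", ties = "ordered")$y
  }
  if (!length(rows)) stop("no trials cover the alignment window")
  list(t_ms = grid, values = do.call(rbind, rows))
}
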