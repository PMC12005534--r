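#' Single-trial sigmoid (change-point) fit of firing rate
#'
#' Least-squares fit of the four-parameter logistic
#' `f(t) = f_I / (1 + exp(-(t - t0)/alpha)) + f_b`
#' to a firing-rate trace approaching the reported intention time. `f_b` and
#' `f_I` are the asymptotic baseline and step rates, `t0` the midpoint time
#' (relative to the reported intention) and `alpha` the steepness scale:
#' large alpha is ramp-like, small alpha step-like.
#'
#' The fit is a deterministic two-stage procedure: a grid over `(t0, alpha)`
#' with the two linear parameters profiled out in closed form, then bounded
#' Levenberg-Marquardt refinement from the best grid start (`f_b >= 0`,
#' `alpha > 0`, `t0` inside the window). `r_squared = 1 - SS_res / SS_tot`;
#' for a nonlinear fit it can be negative, and is reported as-is.
#'
#' @param t_ms Time grid (ms, relative to the reported intention time).
#' @param rate_hz Firing rate at each time.
#' When the rate trace was produced by Gaussian smoothing (as
#' [bin_and_smooth()] does), passing that kernel SD as `smooth_sd_ms` makes
#' the fit use the *smoothed* logistic as its model, so the recovered
#' `alpha` and `t0` describe the underlying rate change rather than the
#' kernel-widened trace.
#'
#' @param t0_grid Candidate midpoints (default: every 50 ms inside the
#'   window, edges excluded).
#' @param alpha_grid Candidate steepness scales (ms).
#' @param smooth_sd_ms SD of the Gaussian kernel the trace was smoothed
#'   with (0 = fit the raw logistic).
#' @return A one-row data frame `(f_I, f_b, t0_ms, alpha_ms, r_squared,
#'   converged)`.
#' @export
fit_sigmoid <- function(t_ms, rate_hz,
                        t0_grid = NULL,
                        alpha_grid = c(5, 10, 20, 40, 80, 160, 320),
                        smooth_sd_ms = 0) {
  stopifnot(length(t_ms) == length(rate_hz), length(t_ms) >= 8)
  lo <- min(t_ms); hi <- max(t_ms)
  if (is.null(t0_grid)) {
    t0_grid <- seq(lo + 25, hi - 25, by = 50)
  }
  y <- rate_hz
  ss_tot <- sum((y - mean(y))^2)
  dt <- if (length(t_ms) > 1) t_ms[2] - t_ms[1] else 1
  kern <- if (smooth_sd_ms > 0) gaussian_kernel_ms(smooth_sd_ms, dt) else NULL
  pad <- if (is.null(kern)) 0L else (length(kern) - 1L) / 2L
  t_ext <- if (pad > 0)
    c(lo - rev(seq_len(pad)) * dt, t_ms, hi + seq_len(pad) * dt)
  else t_ms

  # unit-amplitude logistic basis, smoothed with the data kernel if given
  basis <- function(t0, alpha) {
    s <- 1 / (1 + exp(-(t_ext - t0) / alpha))
    if (!is.null(kern))
      s <- stats::convolve(s, rev(kern), type = "filter")
    s
  }

  profile_rss <- function(t0, alpha) {
    s <- basis(t0, alpha)
    sv <- stats::var(s)
    if (sv < 1e-14) return(list(rss = Inf))
    b1 <- stats::cov(s, y) / sv
    b0 <- mean(y) - b1 * mean(s)
    res <- y - b0 - b1 * s
    list(rss = sum(res^2), f_b = b0, f_I = b1)
  }

  best <- list(rss = Inf)
  for (t0 in t0_grid) for (al in alpha_grid) {
    cand <- profile_rss(t0, al)
    if (cand$rss < best$rss) best <- c(cand, list(t0 = t0, alpha = al))
  }
  if (!is.finite(best$rss)) {
    return(data.frame(f_I = NA_real_, f_b = NA_real_, t0_ms = NA_real_,
                      alpha_ms = NA_real_, r_squared = NA_real_,
                      converged = FALSE))
  }
  start <- list(fI = best$f_I, fb = max(best$f_b, 0),
                t0 = best$t0, alpha = best$alpha)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fI * basis(t0, alpha) + fb,
      start = start,
      lower = c(fI = -Inf, fb = 0, t0 = lo, alpha = 1e-3),
      upper = c(fI = Inf, fb = Inf, t0 = hi, alpha = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    rss <- best$rss
    out <- data.frame(f_I = best$f_I, f_b = best$f_b, t0_ms = best$t0,
                      alpha_ms = best$alpha,
                      r_squared = 1 - rss / ss_tot, converged = FALSE)
    return(out)
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  # grid-dominance guard: the refined optimum may never be worse than the
  # best grid start
  if (rss > best$rss + 1e-9) {
    cf <- c(fI = best$f_I, fb = best$f_b, t0 = best$t0, alpha = best$alpha)
    rss <- best$rss
  }
  data.frame(f_I = unname(cf["fI"]), f_b = unname(cf["fb"]),
             t0_ms = unname(cf["t0"]), alpha_ms = unname(cf["alpha"]),
             r_squared = 1 - rss / ss_tot, converged = TRUE)
}

#' Evaluate the sigmoid model
#'
#' @param t_ms Times (ms).
#' @param f_I,f_b,t0_ms,alpha_ms Model parameters.
#' @return Rate (Hz) at each time.
#' @export
sigmoid_rate <- function(t_ms, f_I, f_b, t0_ms, alpha_ms) {
  f_I / (1 + exp(-(t_ms - t0_ms) / alpha_ms)) + f_b
}

#' Sigmoid fit of a single trial's spike train
#'
#' The recommended single-trial pipeline: a smoothing-aware least-squares
#' fit of the rate trace (see [fit_sigmoid()]) provides starting values and
#' the trace-level `r_squared` used for retention; the parameters are then
#' refined by Poisson maximum likelihood on binned spike counts — the
#' correct noise model for sparse single-trial spiking, which removes most
#' of the bias a Gaussian loss suffers on low-rate data. Fits whose
#' midpoint lands on the window boundary are not identified and are flagged
#' invalid (`converged = FALSE`).
#'
#' @param spike_times_ms Spike times (ms) relative to the reported
#'   intention time.
#' @param window_ms Fit window (default `c(-2000, 200)`: the approach to
#'   the reported intention plus a short tail).
#' @param count_bin_ms Bin width for the Poisson likelihood (default 10).
#' @param smooth_sd_ms Kernel SD for the trace stage (default 50).
#' @param edge_ms Midpoints within this distance of a window edge are
#'   treated as non-identified (default 25).
#' @return A one-row data frame as [fit_sigmoid()].
#' @export
fit_sigmoid_counts <- function(spike_times_ms, window_ms = c(-2000, 200),
                               count_bin_ms = 10, smooth_sd_ms = 50,
                               edge_ms = 25) {
  sm <- bin_and_smooth(spike_times_ms, window_ms, sd_ms = smooth_sd_ms)
  keep <- seq(1, length(sm$t_ms), by = 5)
  ls <- fit_sigmoid(sm$t_ms[keep], sm$rate_hz[keep],
                    smooth_sd_ms = smooth_sd_ms)
  if (is.na(ls$t0_ms)) return(ls)
  edges <- seq(window_ms[1], window_ms[2], by = count_bin_ms)
  cnt <- bin_counts(spike_times_ms, edges)
  tm <- edges[-length(edges)] + count_bin_ms / 2
  nll <- function(par) {
    lam <- sigmoid_rate(tm, par[1], par[2], par[3], par[4]) *
      count_bin_ms / 1000
    lam <- pmax(lam, 1e-9)
    sum(lam - cnt * log(lam))
  }
  o <- tryCatch(
    stats::optim(c(max(ls$f_I, 0.5), max(ls$f_b, 0.1), ls$t0_ms,
                   max(ls$alpha_ms, 2)),
                 nll, method = "L-BFGS-B",
                 lower = c(-1000, 0, window_ms[1], 1),
                 upper = c(1000, 1000, window_ms[2], 1000)),
    error = function(e) NULL)
  if (is.null(o)) {
    ls$converged <- FALSE
    return(ls)
  }
  on_edge <- o$par[3] < window_ms[1] + edge_ms ||
    o$par[3] > window_ms[2] - edge_ms
  data.frame(f_I = o$par[1], f_b = o$par[2], t0_ms = o$par[3],
             alpha_ms = o$par[4], r_squared = ls$r_squared,
             converged = !on_edge)
}

#' Retention and summaries of sigmoid fits
#'
#' Keeps fits with `r_squared` strictly above the threshold (default 0.5)
#' and summarizes the retained midpoint and steepness distributions.
#'
#' @param fits Data frame of rows from [fit_sigmoid()] (any extra columns
#'   such as `trial_id`/`unit_id` are carried through).
#' @param r2_threshold Retention threshold (default 0.5, strict inequality).
#' @return List: `retained` (data frame), `n_retained`, `mean_t0_ms`,
#'   `median_t0_ms`, `mean_alpha_ms`, `median_alpha_ms`.
#' @export
summarize_fits <- function(fits, r2_threshold = 0.5) {
  keep <- !is.na(fits$r_squared) & fits$r_squared > r2_threshold
  if ("converged" %in% names(fits)) keep <- keep & fits$converged
  retained <- fits[keep, , drop = FALSE]
  list(retained = retained, n_retained = nrow(retained),
       mean_t0_ms = if (nrow(retained)) mean(retained$t0_ms) else NA_real_,
       median_t0_ms = if (nrow(retained)) stats::median(retained$t0_ms)
       else NA_real_,
       mean_alpha_ms = if (nrow(retained)) mean(retained$alpha_ms)
       else NA_real_,
       median_alpha_ms = if (nrow(retained)) stats::median(retained$alpha_ms)
       else NA_real_)
}
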