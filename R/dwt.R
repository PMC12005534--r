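# Discrete wavelet transform (Daubechies family, periodized pyramid).
# Standard published filter taps; db4 is the package default order.

DB4_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
            -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
            -0.0328830116668852, -0.010597401785069032)

circ_conv_down2 <- function(x, h) {
  y <- as.numeric(stats::filter(x, h, method = "convolution", sides = 1,
                                circular = TRUE))
  y[seq(2, length(y), by = 2)]
}

#' Discrete wavelet detail coefficients
#'
#' Periodized pyramid decomposition; level `l` details carry the band
#' `fs / 2^(l+1)` to `fs / 2^l`.
#'
#' @param x Numeric signal.
#' @param max_level Deepest level to compute (capped by signal length).
#' @return List of detail-coefficient vectors, one per level.
#' @export
dwt_details <- function(x, max_level = 11) {
  a <- x
  details <- vector("list", max_level)
  for (l in seq_len(max_level)) {
    if (length(a) < length(DB4_LO)) {
      details <- details[seq_len(l - 1)]
      break
    }
    details[[l]] <- circ_conv_down2(a, DB4_HI)
    a <- circ_conv_down2(a, DB4_LO)
  }
  details
}

#' Frequency band of a DWT detail level
#'
#' @param fs Sampling rate (Hz).
#' @param level Decomposition level.
#' @return `c(low, high)` in Hz: `fs/2^(level+1)` to `fs/2^level`.
#' @export
dwt_level_band <- function(fs, level) {
  c(fs / 2^(level + 1), fs / 2^level)
}

#' Mean wavelet power features
#'
#' The movement decoder's feature set: per channel, an 11-level Daubechies
#' decomposition; the squared detail coefficients of levels 3-6 (the
#' multi-unit band, 235 Hz - 3.75 kHz at 30 kHz) are averaged within 100 ms
#' bins, then z-scored per channel against a trailing running baseline,
#' giving one value per channel per bin.
#'
#' @param raw Matrix (samples x channels) of wideband data, in uV.
#' @param fs Sampling rate (Hz, default 30000). If the level-frequency
#'   mapping at this rate no longer covers the multi-unit band, the levels
#'   are recomputed with a warning.
#' @param levels Detail levels to average (default 3:6).
#' @param bin_ms Feature bin width (default 100).
#' @param max_level Decomposition depth (default 11).
#' @param normalize `"zscore"` (trailing baseline) or `"none"` (raw mean
#'   power, used by tests against the filter-bank oracle).
#' @param baseline_bins Length of the trailing baseline in bins (default
#'   100, i.e., 10 s at 100 ms bins).
#' @return List with `t_ms` (bin starts) and `values` (bins x channels).
#' @export
extract_mwp <- function(raw, fs = 30000, levels = 3:6, bin_ms = 100,
                        max_level = 11, normalize = c("zscore", "none"),
                        baseline_bins = 100) {
  normalize <- match.arg(normalize)
  raw <- as.matrix(raw)
  n <- nrow(raw)
  if (n < bin_ms * fs / 1000) stop("snippet shorter than one feature bin")
  if (fs != 30000) {
    target <- c(235, 3750)
    levels <- which(vapply(1:max_level, function(l) {
      b <- dwt_level_band(fs, l)
      b[1] < target[2] && b[2] > target[1]
    }, logical(1)))
    warning(sprintf("fs = %g Hz: multi-unit band remapped to levels %s",
                    fs, paste(levels, collapse = ",")))
  }
  n_bins <- floor(n / (bin_ms * fs / 1000))
  vals <- matrix(0, n_bins, ncol(raw))
  for (ch in seq_len(ncol(raw))) {
    det <- dwt_details(raw[, ch], max_level)
    per_level <- matrix(NA_real_, n_bins, length(levels))
    for (j in seq_along(levels)) {
      l <- levels[j]
      if (l > length(det)) next
      d <- det[[l]]
      # coefficient k at level l sits near sample (k - 1/2) * 2^l
      t_ms <- ((seq_along(d) - 0.5) * 2^l) / fs * 1000
      bin_idx <- pmin(floor(t_ms / bin_ms) + 1L, n_bins)
      per_level[, j] <- as.numeric(
        tapply(d^2, factor(bin_idx, levels = seq_len(n_bins)),
               mean, default = NA))
    }
    vals[, ch] <- rowMeans(per_level, na.rm = TRUE)
  }
  vals[is.nan(vals)] <- 0
  if (normalize == "zscore") {
    for (ch in seq_len(ncol(vals))) {
      v <- vals[, ch]
      z <- numeric(n_bins)
      for (i in seq_len(n_bins)) {
        lo <- max(1L, i - baseline_bins)
        base <- v[lo:i]
        s <- stats::sd(base)
        z[i] <- if (is.na(s) || s == 0) 0 else (v[i] - mean(base)) / s
      }
      vals[, ch] <- z
    }
  }
  list(t_ms = (seq_len(n_bins) - 1L) * bin_ms, values = vals)
}

#' Morlet continuous-wavelet power map
#'
#' Complex Morlet transform (center frequency parameter `omega0 = 6`)
#' evaluated by FFT convolution at each requested frequency; power is the
#' squared modulus, optionally normalized per frequency to a baseline
#' window's mean.
#'
#' @param x Numeric signal (one LFP channel).
#' @param fs Sampling rate (Hz).
#' @param freqs Frequencies to evaluate (Hz).
#' @param baseline_idx Optional sample indices of the normalization window.
#' @return List with `freqs` and `power` (frequencies x samples).
#' @export
morlet_power <- function(x, fs, freqs = seq(0.5, 30, by = 0.5),
                         baseline_idx = NULL) {
  n <- length(x)
  omega0 <- 6
  if (n < 2 * fs / min(freqs) * omega0 / (2 * pi))
    stop("window shorter than two cycles at the lowest frequency")
  X <- stats::fft(x)
  ang <- 2 * pi * (seq_len(n) - 1) / n * fs # FFT bin angular frequencies (rad/s)
  ang[ang > pi * fs] <- ang[ang > pi * fs] - 2 * pi * fs
  pw <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i]) # wavelet scale (s)
    # scaled so a unit-amplitude sine yields the same power at every
    # frequency (band powers are directly comparable)
    psi_hat <- pi^(-0.25) * sqrt(2 * pi * fs) *
      exp(-0.5 * (s * ang - omega0)^2) * (ang > 0)
    w <- stats::fft(X * psi_hat, inverse = TRUE) / n
    pw[i, ] <- Mod(w)^2
  }
  if (!is.null(baseline_idx)) {
    base <- rowMeans(pw[, baseline_idx, drop = FALSE])
    pw <- sweep(pw, 1, pmax(base, .Machine$double.eps), `/`)
  }
  list(freqs = freqs, power = pw)
}
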