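# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. Keeps generator determinism independent of
# surrounding code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying within the
# 32-bit signed integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483587L) + 1L
}

stop_absent <- function(what) {
  stop(sprintf("absent data: %s", what), call. = FALSE)
}

# Discrete Gaussian kernel on a 1 ms grid, truncated at +/- 4 SD and
# normalized to unit sum so convolution conserves spike count.
gaussian_kernel_ms <- function(sd_ms, bin_ms = 1) {
  stopifnot(sd_ms > 0, bin_ms > 0)
  half <- ceiling(4 * sd_ms / bin_ms)
  x <- (-half):half * bin_ms
  k <- exp(-0.5 * (x / sd_ms)^2)
  k / sum(k)
}

# Centered convolution of a vector with a symmetric kernel (edge-padded with
# zeros), returning a vector of the same length.
conv_same <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) / 2L
  out <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(kernel), type = "filter")
  stopifnot(length(out) == n)
  out
}

# Histogram counts on half-open bins [edge_i, edge_{i+1}), robust to empty
# input.
bin_counts <- function(times, edges) {
  n_bins <- length(edges) - 1L
  if (!length(times)) return(integer(n_bins))
  idx <- findInterval(times, edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= n_bins]
  tabulate(idx, nbins = n_bins)
}

# Vectorized two-sample Welch t-test across the columns of two matrices
# (rows = observations, columns = time bins). Returns two-sided p-values.
welch_p_columns <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  stopifnot(na >= 2, nb >= 2, ncol(a) == ncol(b))
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- ifelse(abs(ma - mb)[se2 == 0] > 0, 0, 1)
  p
}
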