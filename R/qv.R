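#' Quadratic-variation statistics of an observed series
#'
#' Computes, per axis, the full quadratic variation
#' `sum((X[k] - X[k-1])^2) / (n h_n)`, the reduced quadratic variation built
#' from two-step increments at even indices
#' `sum((X[2k] - X[2k-2])^2) / (n h_n)` (over `2 <= 2k <= n`; for odd `n` the
#' sum simply stops at the largest even index), and the quartic sum
#' `sum((X[k] - X[k-1])^4)` (not normalised). Under smoothing the full QV is
#' deflated more than the reduced QV, which is what the ratio estimator and
#' the smoothness test exploit.
#'
#' @param series a [convobs_series()].
#' @return object of class `qv_stats`: list with d-vectors `full_qv`,
#'   `reduced_qv`, `quartic_sum` plus `n`, `h_n`.
#' @export
compute_qv_stats <- function(series) {
  if (!inherits(series, "convobs_series")) fail_validation("series must be a convobs_series")
  n <- series$n
  if (n < 4) fail_validation("need at least n = 4 observation steps")
  h <- series$h_n
  dif <- diff(series$values)
  full <- colSums(dif^2) / (n * h)
  quart <- colSums(dif^4)
  even <- series$values[seq(1, n + 1, by = 2), , drop = FALSE]  # rows 0,2,4,... <= n
  dif2 <- diff(even)
  reduced <- colSums(dif2^2) / (n * h)
  structure(list(full_qv = full, reduced_qv = reduced, quartic_sum = quart,
                 n = n, h_n = h), class = "qv_stats")
}

#' Realised volatility with subsampling
#'
#' `RV_k = sum over i of (Y[ik] - Y[(i-1)k])^2`, the sum of squared increments
#' taken every `k`-th observation. For directly observed diffusions `RV_k` is
#' roughly flat in `k`; classical microstructure noise inflates it as `k`
#' decreases, while moving-average smoothing deflates it at high frequency
#' (small `k`) — the diagnostic signature of convolutional observation.
#'
#' @param series a [convobs_series()].
#' @param axis coordinate index.
#' @param k subsampling frequency, `1 <= k <= n`.
#' @return scalar realised volatility.
#' @export
realised_volatility_subsampled <- function(series, axis = 1, k = 1) {
  if (!inherits(series, "convobs_series")) fail_validation("series must be a convobs_series")
  if (axis < 1 || axis > series$d) fail_validation("axis out of range")
  if (k < 1 || k > series$n) fail_validation("k must be in [1, n]")
  y <- series$values[1 + k * (0:(series$n %/% k)), axis]
  sum(diff(y)^2)
}

#' Realised-volatility profile over subsampling frequencies
#'
#' @param series a [convobs_series()].
#' @param axis coordinate index.
#' @param k_max largest subsampling frequency (`<= n`).
#' @return data.frame with columns `k` and `rv`.
#' @export
rv_profile <- function(series, axis = 1, k_max = 100) {
  if (k_max > series$n) fail_validation("k_max must not exceed n")
  ks <- seq_len(k_max)
  data.frame(k = ks, rv = vapply(ks, function(k)
    realised_volatility_subsampled(series, axis, k), numeric(1)))
}
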