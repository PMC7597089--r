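#' Estimate the smoothing parameter from the quadratic-variation ratio
#'
#' Per axis, forms the ratio `R = full_qv / reduced_qv` and inverts the
#' population ratio function [ratio_R()]: ratios at or above 1 map to 0
#' (no smoothing), ratios at or below the lower end of the range map to
#' `rho_bar`, and interior ratios are inverted exactly. The estimator is
#' consistent for the true window length as the sample grows.
#'
#' @param series a [convobs_series()].
#' @param rho_bar upper bound of the admissible window length (> 2).
#' @return object of class `smoothing_estimate`: d-vectors `ratio` and
#'   `rho_hat`, plus `rho_bar`.
#' @export
estimate_rho <- function(series, rho_bar = 100) {
  qv <- compute_qv_stats(series)
  if (any(qv$reduced_qv == 0)) {
    ax <- which(qv$reduced_qv == 0)[1]
    fail_numeric("reduced quadratic variation is zero on axis ", ax,
                 " (constant axis?)")
  }
  ratio <- qv$full_qv / qv$reduced_qv
  lower <- (3 * rho_bar - 1) / (6 * rho_bar - 4)
  rho_hat <- vapply(ratio, function(x) {
    if (x >= 1) 0
    else if (x <= lower) rho_bar
    else ratio_R_inverse(x, rho_bar = rho_bar)
  }, numeric(1))
  structure(list(ratio = ratio, rho_hat = rho_hat, rho_bar = rho_bar),
            class = "smoothing_estimate")
}

#' @export
print.smoothing_estimate <- function(x, ...) {
  cat("<smoothing_estimate>\n")
  print(data.frame(axis = seq_along(x$rho_hat), ratio = x$ratio, rho_hat = x$rho_hat))
  invisible(x)
}

#' Test whether the observation is smoothed
#'
#' Per axis, tests H0: the coordinate is observed directly (window length 0)
#' against H1: it is smoothed (window length > 0), using the normalised gap
#' between full and reduced quadratic variation,
#' `T = sqrt(3 / (2 sum(dX^4))) * (sum(dX^2) - sum(d2X^2))` with `dX` the
#' one-step and `d2X` the even-index two-step increments. Under H0, `T` is
#' asymptotically standard Gaussian; under H1 it diverges to `-Inf`, so H0 is
#' rejected when `T` falls below the lower Gaussian quantile at `alpha_sig`.
#' p-values are one-sided lower-tail, reported per axis without multiplicity
#' correction.
#'
#' @param series a [convobs_series()].
#' @param alpha_sig significance level (default 0.05).
#' @return object of class `smoothness_test`: d-vectors `statistic`,
#'   `p_value`, `reject`, plus `alpha_sig` and the critical value.
#' @export
smoothness_test <- function(series, alpha_sig = 0.05) {
  if (alpha_sig <= 0 || alpha_sig >= 1) fail_validation("alpha_sig must be in (0, 1)")
  qv <- compute_qv_stats(series)
  if (any(qv$quartic_sum == 0)) {
    ax <- which(qv$quartic_sum == 0)[1]
    fail_numeric("quartic sum is zero on axis ", ax)
  }
  nh <- qv$n * qv$h_n
  stat <- sqrt(3 / (2 * qv$quartic_sum)) * nh * (qv$full_qv - qv$reduced_qv)
  crit <- qnorm(alpha_sig)
  structure(list(statistic = stat, p_value = pnorm(stat),
                 reject = stat < crit, alpha_sig = alpha_sig, critical = crit),
            class = "smoothness_test")
}

#' @export
print.smoothness_test <- function(x, ...) {
  cat(sprintf("<smoothness_test> H0: direct observation; reject if T < %.4f (alpha = %g)\n",
              x$critical, x$alpha_sig))
  print(data.frame(axis = seq_along(x$statistic), T = x$statistic,
                   p_value = x$p_value, reject = x$reject))
  if (length(x$statistic) > 1)
    cat("note: per-axis p-values, no multiplicity correction applied\n")
  invisible(x)
}
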