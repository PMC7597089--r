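#' @useDynLib convodiff, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm qnorm rnorm uniroot optim optimize ks.test sd
#' @importFrom utils read.csv write.csv
NULL

# Internal condition helpers: validation errors (bad user input) are kept
# distinct from numeric failures (explosion, non-convergence) so the CLI can
# map them to different exit codes.
fail_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("convodiff_validation_error", "convodiff_error")))
}
fail_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("convodiff_numeric_error", "convodiff_error")))
}

#' Increment-covariance deflation factor of the rectangular smoothing kernel
#'
#' `fG(s, t)` is the factor by which observing two coordinates of a diffusion
#' through rectangular moving-average windows of lengths `s` and `t` (in units
#' of the sampling step) deflates the covariance of their one-step increments,
#' relative to direct observation. `fG(0, 0) = 1` recovers direct observation;
#' on the diagonal `fG(r, r)` is the full quadratic-variation scale factor
#' (see [qv_limit_full()]).
#'
#' The function is piecewise rational with branch seams where either argument
#' crosses 0 or 1 and where the windows stop overlapping (`|s - t| = 1`); it is
#' symmetric and continuous. Each branch is cross-checked against the
#' independent numerical oracle [covariance_oracle()] in the test suite.
#'
#' @param s,t non-negative window lengths, in sampling steps; recycled to a
#'   common length.
#' @param rho_bar upper bound of the admissible window length (must exceed 2).
#' @return numeric vector of deflation factors in (0, 1].
#' @examples
#' fG(0, 0)   # 1: direct observation
#' fG(1, 1)   # 2/3: integrated observation
#' @export
fG <- function(s, t, rho_bar = 100) {
  if (rho_bar <= 2) fail_validation("rho_bar must exceed 2")
  n <- max(length(s), length(t))
  s <- rep_len(as.numeric(s), n)
  t <- rep_len(as.numeric(t), n)
  if (any(!is.finite(s)) || any(!is.finite(t))) fail_validation("fG: arguments must be finite")
  if (any(s < 0 | t < 0 | s > rho_bar | t > rho_bar))
    fail_validation("fG: arguments must lie in [0, rho_bar]")
  vapply(seq_len(n), function(i) fG_scalar(s[i], t[i]), numeric(1))
}

# scalar kernel of fG; assumes domain already checked
fG_scalar <- function(s, t) {
  u <- min(s, t)
  v <- max(s, t)
  if (v == 0) return(1)
  if (u == 0) {
    if (v <= 1) return(1 - v / 2)
    return(1 / (2 * v))
  }
  if (v <= 1)
    return((3 * u^2 * v - 3 * u * v^2 + 6 * u * v - 2 * u^3) / (6 * u * v))
  if (u <= 1) {
    if (v <= u + 1)
      return((-(u - v)^3 + 6 * u * v - u^3 - 3 * v^2 + 3 * v - 1) / (6 * u * v))
    return((3 * u^2 + 3 * u - u^3) / (6 * u * v))
  }
  if (v <= u + 1)
    return((-(u - v)^3 - 3 * u^2 - 3 * v^2 + 6 * u * v + 3 * u + 3 * v - 2) / (6 * u * v))
  (6 * u - 1) / (6 * u * v)
}

#' Limiting one-step increment covariance under convolutional observation
#'
#' Given the infinitesimal covariance `A = a a'` of the latent diffusion at a
#' point, the observed one-step increment covariance converges to
#' `G[i, j] = A[i, j] * fG(rho[i], rho[j])`. This is the target matched by the
#' diffusion-parameter contrast [h1_objective()].
#'
#' @param A symmetric positive semi-definite d x d matrix.
#' @param rho vector of d non-negative window lengths (sampling steps).
#' @param rho_bar admissible upper bound for `rho` (> 2).
#' @return d x d matrix, symmetric PSD.
#' @export
G_matrix <- function(A, rho, rho_bar = 100) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) fail_validation("A must be a square matrix")
  d <- nrow(A)
  rho <- rep_len(as.numeric(rho), d)
  A * outer(rho, rho, function(x, y) fG(x, y, rho_bar = rho_bar))
}

#' Quadratic-variation scale limits
#'
#' `qv_limit_full(rho)` is the in-probability limit of the full quadratic
#' variation (one-step squared increments, normalised by n h) of a coordinate
#' smoothed over a window of `rho` sampling steps, expressed as a multiple of
#' the time-averaged infinitesimal variance; it equals `fG(rho, rho)`.
#' `qv_limit_reduced(rho)` is the corresponding limit for the reduced
#' quadratic variation built from two-step increments at even indices (with
#' the same n h normalisation). The two limits separate exactly when
#' `rho > 0`, which is what makes the ratio [ratio_R()] informative.
#'
#' @param rho non-negative window length(s), in sampling steps.
#' @param rho_bar admissible upper bound (> 2).
#' @return numeric vector of scale factors in (0, 1].
#' @export
qv_limit_full <- function(rho, rho_bar = 100) {
  check_rho_domain(rho, rho_bar)
  ifelse(rho == 0, 1,
    ifelse(rho <= 1, 1 - rho / 3, 1 / rho - 1 / (3 * rho^2)))
}

#' @rdname qv_limit_full
#' @export
qv_limit_reduced <- function(rho, rho_bar = 100) {
  check_rho_domain(rho, rho_bar)
  ifelse(rho == 0, 1,
    ifelse(rho <= 2, 1 - rho / 6, (6 * rho - 4) / (3 * rho^2)))
}

check_rho_domain <- function(rho, rho_bar) {
  if (rho_bar <= 2) fail_validation("rho_bar must exceed 2")
  if (any(!is.finite(rho)) || any(rho < 0 | rho > rho_bar))
    fail_validation("rho must lie in [0, rho_bar]")
  invisible(TRUE)
}

#' Population quadratic-variation ratio and its inverse
#'
#' `ratio_R(rho)` is the limit of full over reduced quadratic variation for a
#' coordinate smoothed over `rho` sampling steps. It is strictly decreasing
#' and continuous on `[0, rho_bar]` with range
#' `((3 rho_bar - 1) / (6 rho_bar - 4), 1]`, so it admits an inverse:
#' `ratio_R_inverse(x)` returns the window length whose population ratio is
#' `x`. The inverse is piecewise: rational closed forms on `x in [4/5, 1)` and
#' `x in (lower, 5/8)`, and a bracketed root of the cubic relation
#' `x (6 y^2 - y^3) = 6 y - 2` on `x in [5/8, 4/5)` (monotone on `y in (1, 2]`,
#' solved to 1e-12).
#'
#' @param rho window length(s) in `[0, rho_bar]`.
#' @param x ratio value(s) strictly inside the range of `ratio_R`.
#' @param rho_bar admissible upper bound (> 2).
#' @return `ratio_R`: ratio values; `ratio_R_inverse`: window lengths.
#' @export
ratio_R <- function(rho, rho_bar = 100) {
  check_rho_domain(rho, rho_bar)
  ifelse(rho == 0, 1,
    ifelse(rho <= 1, (6 - 2 * rho) / (6 - rho),
      ifelse(rho <= 2, (6 * rho - 2) / (6 * rho^2 - rho^3),
        (3 * rho - 1) / (6 * rho - 4))))
}

#' @rdname ratio_R
#' @export
ratio_R_inverse <- function(x, rho_bar = 100) {
  if (rho_bar <= 2) fail_validation("rho_bar must exceed 2")
  lower <- (3 * rho_bar - 1) / (6 * rho_bar - 4)
  if (any(!is.finite(x)) || any(x <= lower | x >= 1))
    fail_validation("ratio_R_inverse: x must lie strictly inside (",
                    format(lower), ", 1)")
  vapply(x, function(xi) {
    if (xi >= 4 / 5) {
      6 * (1 - xi) / (2 - xi)
    } else if (xi >= 5 / 8) {
      # root of x(6y^2 - y^3) = 6y - 2 on (1, 2]; LHS-RHS is monotone there
      uniroot(function(y) xi * (6 * y^2 - y^3) - (6 * y - 2),
              interval = c(1, 2), tol = 1e-12)$root
    } else {
      (4 * xi - 1) / (6 * xi - 3)
    }
  }, numeric(1))
}

#' Numerical oracle for the increment covariance of smoothed Brownian motion
#'
#' Independently verifies the closed forms [fG()] and [qv_limit_reduced()] by
#' direct quadrature. For a standard Brownian motion observed through
#' rectangular windows of `s` and `t` sampling steps, the covariance of
#' increments over `step` sampling steps (divided by `step`) equals the double
#' integral of `min(u, v)` against the product of kernel differences. The
#' kernel-difference factor is piecewise constant over at most two intervals
#' per argument, so the integral is evaluated by trapezoidal quadrature on each
#' rectangle where the integrand is continuous; Dirac (window = 0) axes are
#' integrated out analytically.
#'
#' `covariance_oracle(s, t)` converges to `fG(s, t)` as `n_grid` grows;
#' `covariance_oracle(r, r, step = 2)` converges to `qv_limit_reduced(r)`.
#'
#' @param s,t non-negative window lengths (sampling steps).
#' @param n_grid quadrature nodes per axis and rectangle (>= 10).
#' @param step increment length in sampling steps (1 = full QV, 2 = reduced).
#' @return scalar covariance factor.
#' @export
covariance_oracle <- function(s, t, n_grid = 2000, step = 1) {
  if (s < 0 || t < 0) fail_validation("covariance_oracle: s, t must be non-negative")
  if (n_grid < 10) fail_validation("covariance_oracle: n_grid too small")
  if (step <= 0) fail_validation("covariance_oracle: step must be positive")
  Delta <- max(s, t, 1)  # any anchor >= max(s, t) gives the stationary value
  if (s == 0 && t == 0) return(1)
  # interval pairs on which the kernel difference of a width-w window is +/- 1/w
  win <- function(w) list(plus = c(Delta + step - w, Delta + step),
                          minus = c(Delta - w, Delta))
  if (s == 0 || t == 0) {
    w <- max(s, t)
    iv <- win(w)
    # the Dirac axis contributes phi(v) = min(Delta + step, v) - min(Delta, v)
    phi <- function(v) pmin(Delta + step, v) - pmin(Delta, v)
    trap1 <- function(a, b) {
      g <- seq(a, b, length.out = n_grid + 1)
      wt <- rep(1, n_grid + 1); wt[c(1, n_grid + 1)] <- 0.5
      (b - a) / n_grid * sum(wt * phi(g))
    }
    return((trap1(iv$plus[1], iv$plus[2]) - trap1(iv$minus[1], iv$minus[2])) / (w * step))
  }
  ivs <- win(s); ivt <- win(t)
  trap2 <- function(I, J) {
    u <- seq(I[1], I[2], length.out = n_grid + 1)
    v <- seq(J[1], J[2], length.out = n_grid + 1)
    wt <- rep(1, n_grid + 1); wt[c(1, n_grid + 1)] <- 0.5
    du <- (I[2] - I[1]) / n_grid
    dv <- (J[2] - J[1]) / n_grid
    du * dv * drop(wt %*% outer(u, v, pmin) %*% wt)
  }
  val <- trap2(ivs$plus, ivt$plus) - trap2(ivs$plus, ivt$minus) -
    trap2(ivs$minus, ivt$plus) + trap2(ivs$minus, ivt$minus)
  val / (s * t * step)
}
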