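#' Specify a parametric diffusion model
#'
#' Bundles the drift `b(x, beta)`, the diffusion coefficient `a(x, alpha)`,
#' the state/noise dimensions and the compact box parameter spaces over which
#' the quasi-likelihood contrasts are maximised.
#'
#' Optional structure flags unlock exact fast paths used by the estimators
#' (the generic multi-start optimiser is always available and is cross-checked
#' against them in the tests):
#' \describe{
#'   \item{`linear`}{`function(alpha, beta)` returning `list(B, c, S)` with
#'     drift `B x + c` and constant diffusion matrix `S`; enables the compiled
#'     Euler-Maruyama loop.}
#'   \item{`diffusion_constant`}{`TRUE` if `a(x, alpha)` does not depend on
#'     `x`; the diffusion contrast then reduces to sufficient statistics.}
#'   \item{`alpha_identity`}{`TRUE` if `d = 1` and `a(x, alpha) = alpha`
#'     (scalar); the diffusion estimate then has a closed form.}
#'   \item{`drift_design`}{`function(X)` mapping an N x d matrix of states to
#'     the (N d) x m2 design matrix of a drift linear in `beta` (rows of each
#'     observation stacked in axis order); enables least-squares drift fits.}
#' }
#'
#' @param d state dimension.
#' @param r driving-noise dimension.
#' @param drift `function(x, beta)` returning a d-vector.
#' @param diffusion `function(x, alpha)` returning a d x r matrix.
#' @param theta1_box m1 x 2 matrix of (lower, upper) bounds for `alpha`.
#' @param theta2_box m2 x 2 matrix of (lower, upper) bounds for `beta`.
#' @param linear,diffusion_constant,alpha_identity,drift_design optional
#'   structure hooks, see Details.
#' @return an object of class `diffusion_model`.
#' @export
diffusion_model <- function(d, r, drift, diffusion, theta1_box, theta2_box,
                            linear = NULL, diffusion_constant = FALSE,
                            alpha_identity = FALSE, drift_design = NULL) {
  theta1_box <- as_box(theta1_box, "theta1_box")
  theta2_box <- as_box(theta2_box, "theta2_box")
  if (!is.function(drift) || !is.function(diffusion))
    fail_validation("drift and diffusion must be functions")
  if (d < 1 || r < 1) fail_validation("dimensions must be positive")
  structure(
    list(d = as.integer(d), r = as.integer(r), drift = drift, diffusion = diffusion,
         theta1_box = theta1_box, theta2_box = theta2_box, linear = linear,
         diffusion_constant = isTRUE(diffusion_constant),
         alpha_identity = isTRUE(alpha_identity), drift_design = drift_design),
    class = "diffusion_model"
  )
}

as_box <- function(box, name) {
  box <- as.matrix(box)
  if (ncol(box) != 2) fail_validation(name, " must have two columns (lower, upper)")
  if (any(!is.finite(box))) fail_validation(name, " must be finite (compact)")
  if (any(box[, 1] >= box[, 2])) fail_validation(name, ": lower bounds must be < upper bounds")
  unname(box)
}

in_box <- function(par, box, tol = 1e-8) {
  length(par) == nrow(box) && all(par >= box[, 1] - tol) && all(par <= box[, 2] + tol)
}

clamp_box <- function(par, box) pmin(pmax(par, box[, 1]), box[, 2])

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("<diffusion_model> d = %d, r = %d, m1 = %d, m2 = %d\n",
              x$d, x$r, nrow(x$theta1_box), nrow(x$theta2_box)))
  invisible(x)
}

#' Ornstein-Uhlenbeck model presets
#'
#' `ou_preset_1d()` is the scalar OU model `dX = (beta1 X + beta2) dt + alpha dw`
#' with `alpha` in \[0.01, 10\] and `beta` in \[-10, -0.01\] x \[-10, 10\].
#' `ou_preset_2d()` is the bivariate OU model with linear drift
#' `(beta1, beta2; beta4, beta5) x + (beta3, beta6)` and symmetric constant
#' diffusion matrix `(alpha1, alpha2; alpha2, alpha3)`, with boxes
#' \[1 + 1e-8, 10\] x \[-1 + 1e-8, 1 - 1e-8\] x \[1 + 1e-8, 10\] for `alpha`
#' and \[-10, 10\]^6 for `beta`. Both are the standard test beds for the
#' convolution-corrected estimators.
#'
#' @return a [diffusion_model()].
#' @export
ou_preset_1d <- function() {
  diffusion_model(
    d = 1, r = 1,
    drift = function(x, beta) beta[1] * x + beta[2],
    diffusion = function(x, alpha) matrix(alpha[1], 1, 1),
    theta1_box = cbind(0.01, 10),
    theta2_box = rbind(c(-10, -0.01), c(-10, 10)),
    linear = function(alpha, beta) {
      list(B = matrix(beta[1], 1, 1), c = beta[2], S = matrix(alpha[1], 1, 1))
    },
    diffusion_constant = TRUE,
    alpha_identity = TRUE,
    drift_design = function(X) cbind(X[, 1], 1)
  )
}

#' @rdname ou_preset_1d
#' @export
ou_preset_2d <- function() {
  diffusion_model(
    d = 2, r = 2,
    drift = function(x, beta) {
      c(beta[1] * x[1] + beta[2] * x[2] + beta[3],
        beta[4] * x[1] + beta[5] * x[2] + beta[6])
    },
    diffusion = function(x, alpha) {
      matrix(c(alpha[1], alpha[2], alpha[2], alpha[3]), 2, 2)
    },
    theta1_box = rbind(c(1 + 1e-8, 10), c(-1 + 1e-8, 1 - 1e-8), c(1 + 1e-8, 10)),
    theta2_box = matrix(rep(c(-10, 10), each = 6), 6, 2),
    linear = function(alpha, beta) {
      list(B = matrix(beta[c(1, 4, 2, 5)], 2, 2), c = beta[c(3, 6)],
           S = matrix(alpha[c(1, 2, 2, 3)], 2, 2))
    },
    diffusion_constant = TRUE,
    drift_design = function(X) {
      n <- nrow(X)
      D <- matrix(0, 2 * n, 6)
      odd <- seq(1, 2 * n, by = 2)
      D[odd, 1:2] <- X
      D[odd, 3] <- 1
      D[odd + 1, 4:5] <- X
      D[odd + 1, 6] <- 1
      D
    }
  )
}
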