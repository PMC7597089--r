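# Small bespoke models used by the unit tests.

# driftless unit-scale model with compiled path: observed through a window,
# its increment variance is governed purely by the kernel factor
brownian_model <- function() {
  diffusion_model(
    d = 1, r = 1,
    drift = function(x, beta) 0 * x,
    diffusion = function(x, alpha) matrix(alpha[1], 1, 1),
    theta1_box = cbind(0.5, 2),
    theta2_box = cbind(-1, 1),
    linear = function(alpha, beta) {
      list(B = matrix(0, 1, 1), c = 0, S = matrix(alpha[1], 1, 1))
    },
    diffusion_constant = TRUE, alpha_identity = TRUE
  )
}

# generic-path model (no linear hook): noiseless linear drift when alpha = 0
ode_model <- function() {
  diffusion_model(
    d = 1, r = 1,
    drift = function(x, beta) beta[1] * x,
    diffusion = function(x, alpha) matrix(alpha[1], 1, 1),
    theta1_box = cbind(-1, 1),
    theta2_box = cbind(-5, 5)
  )
}

# model whose drift does not depend on beta at all
zero_drift_model <- function() {
  diffusion_model(
    d = 1, r = 1,
    drift = function(x, beta) 0,
    diffusion = function(x, alpha) matrix(alpha[1], 1, 1),
    theta1_box = cbind(0.5, 2),
    theta2_box = cbind(-1, 1)
  )
}
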