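#' Simulation configuration
#'
#' Collects the observation design (`n` observations at step `h_n`), the
#' refinement exponent `m` (fine simulation step `h_sim = h_n * 10^-m`), the
#' burn-in and the PRNG seed. The burn-in covers the convolution window that
#' reaches back before time 0: if `burn_in_steps` is `NULL` it is resolved at
#' simulation time as `(ceiling(max(rho)) + 1) * 10^m` fine steps, i.e. the
#' process is started at `-lambda` with `lambda = (ceiling(max(rho)) + 1) * h_n`.
#'
#' @param n number of observation steps (the series has `n + 1` rows).
#' @param h_n observation step, in time units.
#' @param m refinement exponent (`m >= 1`).
#' @param x0 initial state at time `-lambda` (recycled to the state dimension).
#' @param burn_in_steps fine steps simulated before time 0, or `NULL`.
#' @param seed integer PRNG seed, or `NULL` to use the current RNG state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n, h_n, m = 2, x0 = 0, burn_in_steps = NULL, seed = NULL) {
  if (n < 2) fail_validation("n must be at least 2")
  if (h_n <= 0) fail_validation("h_n must be positive")
  if (m < 1) fail_validation("m must be at least 1")
  if (!is.null(burn_in_steps) && burn_in_steps < 0)
    fail_validation("burn_in_steps must be non-negative")
  structure(
    list(n = as.integer(n), h_n = h_n, m = as.integer(m),
         h_sim = h_n * 10^(-as.integer(m)), x0 = x0,
         burn_in_steps = if (is.null(burn_in_steps)) NULL else as.integer(burn_in_steps),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

resolve_burn_in <- function(cfg, rho) {
  if (!is.null(cfg$burn_in_steps)) return(cfg$burn_in_steps)
  as.integer((ceiling(max(rho)) + 1) * 10^cfg$m)
}

#' Euler-Maruyama simulation of the latent diffusion
#'
#' Iterates `X[k+1] = X[k] + b(X[k], beta) h_sim + a(X[k], alpha) sqrt(h_sim) Z[k]`
#' with iid standard Gaussian `Z[k]` over the burn-in plus `n * 10^m` fine
#' steps. Models carrying the `linear` hook run in compiled code; arbitrary
#' models fall back to a pure-R loop drawing from the same RNG stream, so both
#' paths coincide under a fixed seed.
#'
#' @param model a [diffusion_model()].
#' @param alpha,beta parameter vectors inside the model boxes.
#' @param cfg a [sim_config()].
#' @param burn_in_steps burn-in override (defaults to the config resolution
#'   with `rho = 0`).
#' @return matrix of `burn_in + n * 10^m + 1` fine states (one row per step).
#' @export
euler_maruyama <- function(model, alpha, beta, cfg, burn_in_steps = NULL) {
  if (!inherits(model, "diffusion_model")) fail_validation("model must be a diffusion_model")
  if (!in_box(alpha, model$theta1_box)) fail_validation("alpha outside theta1_box")
  if (!in_box(beta, model$theta2_box)) fail_validation("beta outside theta2_box")
  burn <- if (is.null(burn_in_steps)) resolve_burn_in(cfg, 0) else as.integer(burn_in_steps)
  nsteps <- burn + cfg$n * 10^cfg$m
  sp <- rng_seed_pair(cfg$seed)
  x0 <- rep_len(as.numeric(cfg$x0), model$d)
  if (!is.null(model$linear)) {
    lin <- model$linear(alpha, beta)
    em_affine_cpp(as.matrix(lin$B), as.numeric(lin$c), as.matrix(lin$S),
                  x0, cfg$h_sim, nsteps, sp[1], sp[2])
  } else {
    em_generic(model, alpha, beta, x0, cfg$h_sim, nsteps, sp)
  }
}

# The fine-path normals come from a compiled xoshiro256++/polar generator whose
# two 31-bit seeds are drawn from R's RNG stream, so set.seed() governs
# everything while the 10^7-step loops stay cheap.
rng_seed_pair <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483647L, 2)
}

# reference pure-R loop for arbitrary drift/diffusion (small n only); consumes
# the same normal stream as the compiled path so both coincide under one seed
em_generic <- function(model, alpha, beta, x0, h, nsteps, seed_pair) {
  d <- model$d
  r <- model$r
  z_all <- rng_normals_cpp(nsteps * r, seed_pair[1], seed_pair[2])
  out <- matrix(NA_real_, nsteps + 1, d)
  x <- x0
  out[1, ] <- x
  sqh <- sqrt(h)
  for (k in seq_len(nsteps)) {
    z <- z_all[(k - 1) * r + seq_len(r)]
    a <- matrix(model$diffusion(x, alpha), d, r)
    x <- x + model$drift(x, beta) * h + sqh * drop(a %*% z)
    if (any(!is.finite(x)))
      fail_numeric("non-finite state (explosion) at fine step ", k)
    out[k + 1, ] <- x
  }
  out
}

#' Convolutional observations from a fine path
#'
#' Produces the observed series: per axis, the trailing moving average of the
#' fine path over a window of `K = round(10^m * rho)` fine steps ending at each
#' observation time (left-endpoint Riemann approximation of the rectangular
#' kernel integral). Axes with `10^m * rho < 1` are observed directly.
#'
#' @param fine_path matrix from [euler_maruyama()].
#' @param cfg the [sim_config()] used to generate it.
#' @param rho vector of window lengths in sampling steps (recycled to d).
#' @param burn_in_steps burn-in actually used for `fine_path` (defaults to the
#'   config resolution for this `rho`).
#' @return a `convobs_series` of `n + 1` observations.
#' @export
convolve_observations <- function(fine_path, cfg, rho, burn_in_steps = NULL) {
  d <- ncol(fine_path)
  rho <- rep_len(as.numeric(rho), d)
  if (any(rho < 0)) fail_validation("rho must be non-negative")
  burn <- if (is.null(burn_in_steps)) resolve_burn_in(cfg, rho) else as.integer(burn_in_steps)
  stride <- 10^cfg$m
  pos <- burn + (0:cfg$n) * stride + 1L
  if (max(pos) > nrow(fine_path))
    fail_validation("fine path too short for the requested observation grid")
  vals <- matrix(NA_real_, cfg$n + 1, d)
  for (l in seq_len(d)) {
    K <- round(stride * rho[l])
    if (stride * rho[l] >= 1) {
      if (K > burn + 1)
        fail_validation("convolution window exceeds the available burn-in (axis ", l, ")")
      vals[, l] <- conv_mean_cpp(fine_path[, l], as.integer(pos), as.integer(K))
    } else {
      vals[, l] <- fine_path[pos, l]
    }
  }
  convobs_series(vals, cfg$h_n)
}

#' Simulate a convolutionally observed diffusion
#'
#' Composition of [euler_maruyama()] and [convolve_observations()]:
#' deterministic given `cfg$seed`.
#'
#' @inheritParams euler_maruyama
#' @param rho smoothing parameter vector (window lengths in sampling steps).
#' @return a `convobs_series`.
#' @export
simulate_convobs <- function(model, alpha, beta, rho, cfg) {
  rho <- rep_len(as.numeric(rho), model$d)
  if (any(rho < 0)) fail_validation("rho must be non-negative")
  burn <- resolve_burn_in(cfg, rho)
  if (!is.null(model$linear)) {
    # fused compiled path: identical output to euler_maruyama() +
    # convolve_observations() but without materialising the fine path
    if (!in_box(alpha, model$theta1_box)) fail_validation("alpha outside theta1_box")
    if (!in_box(beta, model$theta2_box)) fail_validation("beta outside theta2_box")
    sp <- rng_seed_pair(cfg$seed)
    lin <- model$linear(alpha, beta)
    stride <- 10^cfg$m
    K <- ifelse(stride * rho >= 1, as.integer(round(stride * rho)), 0L)
    vals <- sim_convobs_affine_cpp(as.matrix(lin$B), as.numeric(lin$c), as.matrix(lin$S),
                                   rep_len(as.numeric(cfg$x0), model$d), cfg$h_sim,
                                   burn, cfg$n, as.integer(stride), as.integer(K),
                                   sp[1], sp[2])
    return(convobs_series(vals, cfg$h_n))
  }
  fine <- euler_maruyama(model, alpha, beta, cfg, burn_in_steps = burn)
  convolve_observations(fine, cfg, rho, burn_in_steps = burn)
}

#' Observed series container
#'
#' An `(n + 1) x d` matrix of regularly sampled observations together with the
#' sampling step `h_n`.
#'
#' @param values numeric matrix (or vector for d = 1), one row per time point.
#' @param h_n sampling step in time units.
#' @return object of class `convobs_series` with fields `values`, `h_n`,
#'   `n`, `d`.
#' @export
convobs_series <- function(values, h_n) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) fail_validation("series contains missing or non-finite values")
  if (nrow(values) < 3) fail_validation("series must contain at least 3 observations")
  if (h_n <= 0) fail_validation("h_n must be positive")
  structure(list(values = unname(values), h_n = h_n,
                 n = nrow(values) - 1L, d = ncol(values)),
            class = "convobs_series")
}

#' @export
print.convobs_series <- function(x, ...) {
  cat(sprintf("<convobs_series> n = %d, d = %d, h_n = %.6g (T = %.4g)\n",
              x$n, x$d, x$h_n, x$n * x$h_n))
  invisible(x)
}

#' Read and write observed series as delimited text
#'
#' The on-disk format is a CSV with header `t,x1,...,xd`; the time column is
#' `i * h_n`. `write_series()` stores full double precision, so a write/read
#' round trip reproduces the values exactly.
#'
#' @param series a `convobs_series`.
#' @param path file path.
#' @param h_n sampling step; if `NULL`, recovered from the time column.
#' @return `read_series()`: a `convobs_series`; `write_series()`: `path`,
#'   invisibly.
#' @export
write_series <- function(series, path) {
  df <- data.frame(t = (0:series$n) * series$h_n, series$values)
  names(df) <- c("t", paste0("x", seq_len(series$d)))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, h_n = NULL) {
  if (!file.exists(path)) fail_validation("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, header = TRUE),
                 error = function(e) fail_validation("cannot parse series file: ",
                                                     conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2) fail_validation("series file is empty or has no axes")
  if (!all(vapply(df, is.numeric, logical(1))))
    fail_validation("series file contains non-numeric cells")
  has_t <- names(df)[1] == "t"
  vals <- as.matrix(if (has_t) df[, -1, drop = FALSE] else df)
  if (is.null(h_n)) {
    if (!has_t || nrow(df) < 2)
      fail_validation("h_n not given and no time column to recover it from")
    h_n <- df$t[2] - df$t[1]
  }
  convobs_series(vals, h_n)
}
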