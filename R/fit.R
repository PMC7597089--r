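# ---- sufficient statistics for the diffusion contrast ----
# S_k = (dX_k dX_k') / h; for constant-diffusion models the contrast
# -sum ||S_k - G||^2 depends on the data only through sum S_k and sum ||S_k||^2.
h1_suffstats <- function(series) {
  dif <- diff(series$values)
  h <- series$h_n
  d <- series$d
  Tm <- matrix(0, d, d)
  S2 <- 0
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      p <- dif[, i] * dif[, j] / h
      Tm[i, j] <- sum(p)
      S2 <- S2 + sum(p^2)
    }
  }
  list(T = Tm, S2 = S2, n = series$n)
}

model_A <- function(model, x, alpha) {
  a <- matrix(model$diffusion(x, alpha), model$d, model$r)
  a %*% t(a)
}

#' Least-square quasi-likelihood contrast for the diffusion parameter
#'
#' `H1(alpha | rho) = -sum_k || (dX_k dX_k') / h_n - G(X_{k-1}, alpha | rho) ||_F^2`,
#' where `G(x, alpha | rho) = A(x, alpha)` entrywise-times `fG(rho_i, rho_j)`
#' corrects the increment covariance target for the smoothing kernel. At
#' `rho = 0` it reduces to the standard quadratic-variation contrast. The
#' maximiser over the compact box is the convolution-corrected diffusion
#' estimator.
#'
#' @param series a [convobs_series()].
#' @param alpha diffusion parameter inside the model's `theta1_box`.
#' @param rho smoothing parameter vector (recycled to d).
#' @param model a [diffusion_model()].
#' @param rho_bar admissible upper bound for `rho`.
#' @return scalar contrast value (always `<= 0`).
#' @export
h1_objective <- function(series, alpha, rho, model, rho_bar = 100) {
  if (!in_box(alpha, model$theta1_box)) fail_validation("alpha outside theta1_box")
  rho <- rep_len(as.numeric(rho), model$d)
  fmat <- outer(rho, rho, function(x, y) fG(x, y, rho_bar = rho_bar))
  if (model$diffusion_constant) {
    ss <- h1_suffstats(series)
    G <- model_A(model, series$values[1, ], alpha) * fmat
    val <- -(ss$S2 - 2 * sum(ss$T * G) + ss$n * sum(G^2))
    return(min(val, 0))
  }
  dif <- diff(series$values)
  h <- series$h_n
  tot <- 0
  for (k in seq_len(series$n)) {
    S <- tcrossprod(dif[k, ]) / h
    G <- model_A(model, series$values[k, ], alpha) * fmat
    tot <- tot + sum((S - G)^2)
  }
  -tot
}

# lag of the drift contrast: the drift must be evaluated at a state whose
# convolution window predates the increment, hence ceil(max rho) + 1 steps back
h2_lag <- function(rho) as.integer(ceiling(max(rho)) + 1)

# stacked increments and lagged states for the drift contrast
h2_parts <- function(series, lag) {
  n <- series$n
  if (n <= lag + 1) fail_validation("series too short for drift lag ", lag)
  ks <- (lag + 1):n
  U <- series$values[ks + 1, , drop = FALSE] - series$values[ks, , drop = FALSE]
  L <- series$values[ks - lag, , drop = FALSE]
  list(U = U, L = L, ks = ks)
}

#' Least-square quasi-likelihood contrast for the drift parameter
#'
#' `H2(beta | rho) = -(1/h_n) sum_k || dX_k - h_n b(X_{k-1-j}, beta) ||^2`
#' with lag `j = ceiling(max(rho)) + 1`, summed over `k = j+1, ..., n`. The
#' drift is evaluated `j` observation steps behind the increment so that its
#' argument predates the convolution window of the increment's left endpoint.
#'
#' @inheritParams h1_objective
#' @param beta drift parameter inside the model's `theta2_box`.
#' @param lag drift lag override (`NULL` = derive from `rho`; `0` gives the
#'   naive one-lag contrast used by [lga_fit()]).
#' @return scalar contrast value (always `<= 0`).
#' @export
h2_objective <- function(series, beta, rho, model, lag = NULL) {
  if (!in_box(beta, model$theta2_box)) fail_validation("beta outside theta2_box")
  rho <- rep_len(as.numeric(rho), model$d)
  if (is.null(lag)) lag <- h2_lag(rho)
  p <- h2_parts(series, lag)
  h <- series$h_n
  if (!is.null(model$drift_design)) {
    D <- model$drift_design(p$L)
    y <- as.vector(t(p$U))
    r <- y - h * as.vector(D %*% beta)
    return(-sum(r^2) / h)
  }
  tot <- 0
  for (i in seq_len(nrow(p$U))) {
    r <- p$U[i, ] - h * model$drift(p$L[i, ], beta)
    tot <- tot + sum(r^2)
  }
  -tot / h
}

# ---- deterministic box-constrained maximiser ----
# coarse grid of starts + L-BFGS-B refinement + Newton polish on smooth optima;
# ties broken by first start index. fn is maximised.
maximise_box <- function(fn, box, extra_starts = NULL, grid_pts = 5) {
  m <- nrow(box)
  axis_pts <- lapply(seq_len(m), function(i) {
    w <- box[i, 2] - box[i, 1]
    seq(box[i, 1] + 0.05 * w, box[i, 2] - 0.05 * w, length.out = grid_pts)
  })
  starts <- if (m <= 3) {
    as.matrix(expand.grid(axis_pts))
  } else {
    # centre plus one-axis sweeps to keep the start count linear in dimension
    ctr <- rowMeans(box)
    sw <- do.call(rbind, lapply(seq_len(m), function(i) {
      s <- matrix(rep(ctr, each = grid_pts), grid_pts, m)
      s[, i] <- axis_pts[[i]]
      s
    }))
    rbind(ctr, sw)
  }
  if (!is.null(extra_starts)) starts <- rbind(as.matrix(extra_starts), starts)
  neg <- function(par) -fn(par)
  best <- NULL
  n_ok <- 0
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[s, ], neg, method = "L-BFGS-B",
            lower = box[, 1], upper = box[, 2],
            control = list(factr = 10, pgtol = 1e-14, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  if (is.null(best)) fail_numeric("all optimiser starts failed")
  par <- unname(newton_polish(neg, best$par, box))
  list(par = par, value = fn(par), n_starts = nrow(starts),
       n_converged = n_ok, boundary = any(par <= box[, 1] + 1e-10 | par >= box[, 2] - 1e-10))
}

# a few Newton steps on the numeric gradient to polish smooth interior optima
newton_polish <- function(neg, par, box, iter = 8) {
  m <- length(par)
  for (it in seq_len(iter)) {
    eps <- 1e-6 * (1 + abs(par))
    g <- vapply(seq_len(m), function(i) {
      e <- rep(0, m); e[i] <- eps[i]
      (neg(clamp_box(par + e, box)) - neg(clamp_box(par - e, box))) / (2 * eps[i])
    }, numeric(1))
    H <- tryCatch(stats::optimHess(par, neg), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- clamp_box(par - step, box)
    if (neg(cand) <= neg(par)) par <- cand else break
    if (max(abs(step)) < 1e-12) break
  }
  par
}

#' Estimate the diffusion parameter
#'
#' Maximises [h1_objective()] over the model's `theta1_box` by a deterministic
#' multi-start grid plus bounded quasi-Newton refinement. For scalar models
#' with `a(x, alpha) = alpha` the maximiser has the closed form
#' `alpha^2 = full_qv / fG(rho, rho)` (clamped to the box), which is used
#' directly and agrees with the generic optimiser.
#'
#' @inheritParams h1_objective
#' @param use_closed_form use the closed-form fast path when available.
#' @return list with `par`, `value` and optimiser diagnostics.
#' @export
estimate_alpha <- function(series, rho, model, rho_bar = 100, use_closed_form = TRUE) {
  rho <- rep_len(as.numeric(rho), model$d)
  box <- model$theta1_box
  if (use_closed_form && model$alpha_identity && model$d == 1 && nrow(box) == 1) {
    qv <- compute_qv_stats(series)
    g <- fG(rho, rho, rho_bar = rho_bar)
    a <- clamp_box(sqrt(max(qv$full_qv[1] / g, 0)), box)
    return(list(par = a, value = h1_objective(series, a, rho, model, rho_bar),
                n_starts = 0, n_converged = NA_integer_,
                boundary = a <= box[1, 1] + 1e-10 || a >= box[1, 2] - 1e-10,
                method = "closed_form"))
  }
  if (model$diffusion_constant) {
    ss <- h1_suffstats(series)
    fmat <- outer(rho, rho, function(x, y) fG(x, y, rho_bar = rho_bar))
    x1 <- series$values[1, ]
    fn <- function(par) {
      G <- model_A(model, x1, par) * fmat
      -(ss$S2 - 2 * sum(ss$T * G) + ss$n * sum(G^2))
    }
  } else {
    fn <- function(par) h1_objective(series, par, rho, model, rho_bar)
  }
  out <- maximise_box(fn, box)
  out$method <- "multi_start"
  out
}

#' Estimate the drift parameter
#'
#' Maximises [h2_objective()] over the model's `theta2_box`. For drift
#' families linear in `beta` (via the model's `drift_design` hook) the
#' unconstrained maximiser is an exact least-squares solution; it is clamped
#' to the box and, if clamping binds, refined by the bounded multi-start
#' optimiser. Arbitrary drifts use the multi-start optimiser throughout.
#'
#' @inheritParams h2_objective
#' @param use_closed_form use the least-squares fast path when available.
#' @return list with `par`, `value` and optimiser diagnostics.
#' @export
estimate_beta <- function(series, rho, model, lag = NULL, use_closed_form = TRUE) {
  rho <- rep_len(as.numeric(rho), model$d)
  if (is.null(lag)) lag <- h2_lag(rho)
  box <- model$theta2_box
  p <- h2_parts(series, lag)
  h <- series$h_n
  if (!is.null(model$drift_design)) {
    D <- model$drift_design(p$L)
    y <- as.vector(t(p$U))
    # sufficient statistics of the quadratic contrast
    DtD <- crossprod(D)
    Dty <- crossprod(D, y)
    yty <- sum(y^2)
    ols <- tryCatch(drop(solve(DtD, Dty)) / h, error = function(e) NULL)
    if (use_closed_form && !is.null(ols) && all(is.finite(ols)) && in_box(ols, box, tol = 0)) {
      val <- -(yty - 2 * h * sum(ols * Dty) + h^2 * drop(crossprod(ols, DtD %*% ols))) / h
      return(list(par = unname(ols), value = val, n_starts = 0,
                  n_converged = NA_integer_, boundary = FALSE, method = "least_squares"))
    }
    extra <- if (!is.null(ols) && all(is.finite(ols))) clamp_box(ols, box) else NULL
    fn2 <- function(par) -(yty - 2 * h * sum(par * Dty) +
                             h^2 * drop(crossprod(par, DtD %*% par))) / h
    out <- maximise_box(fn2, box, extra_starts = if (is.null(extra)) NULL else rbind(extra))
    out$method <- "multi_start"
    return(out)
  }
  fn <- function(par) h2_objective(series, par, rho, model, lag = lag)
  out <- maximise_box(fn, box)
  out$method <- "multi_start"
  out
}

#' Fit the diffusion and drift parameters of a convolutionally observed diffusion
#'
#' Runs the full plug-in scheme: estimate the smoothing parameter per axis
#' (unless a known `rho` is supplied), then maximise the convolution-corrected
#' contrasts [h1_objective()] and [h2_objective()] over the model's boxes.
#'
#' @param series a [convobs_series()].
#' @param model a [diffusion_model()].
#' @param rho known smoothing parameter; `NULL` (default) estimates it first.
#' @param rho_bar admissible upper bound for the smoothing parameter.
#' @return object of class `param_estimate` with fields `alpha_hat`,
#'   `beta_hat`, `rho_used`, `rho_estimated`, `h1_value`, `h2_value`,
#'   `optimiser_info`, `boundary_rho` and `method`.
#' @export
fit_diffusion <- function(series, model, rho = NULL, rho_bar = 100) {
  rho_estimated <- is.null(rho)
  if (rho_estimated) {
    est <- estimate_rho(series, rho_bar = rho_bar)
    rho <- est$rho_hat
  } else {
    rho <- rep_len(as.numeric(rho), model$d)
    check_rho_domain(rho, rho_bar)
  }
  a <- estimate_alpha(series, rho, model, rho_bar = rho_bar)
  b <- estimate_beta(series, rho, model)
  structure(list(alpha_hat = a$par, beta_hat = b$par, rho_used = rho,
                 rho_estimated = rho_estimated,
                 h1_value = a$value, h2_value = b$value,
                 optimiser_info = list(alpha = a[c("method", "n_starts", "n_converged", "boundary")],
                                       beta = b[c("method", "n_starts", "n_converged", "boundary")]),
                 boundary_rho = any(rho >= rho_bar - 1e-10),
                 method = "convobs"),
            class = "param_estimate")
}

#' Naive local-Gaussian-approximation fit
#'
#' The standard quasi-likelihood fit for directly observed diffusions: the
#' diffusion contrast with no convolution correction (identical to
#' [h1_objective()] at `rho = 0`) and the one-lag drift contrast
#' `-(1/h_n) sum_k || dY_k - h_n b(Y_{k-1}, beta) ||^2`. Used as the baseline
#' that is biased when the observation is in fact smoothed.
#'
#' @inheritParams fit_diffusion
#' @return a `param_estimate` with `method = "lga"`.
#' @export
lga_fit <- function(series, model) {
  zero <- rep(0, model$d)
  a <- estimate_alpha(series, zero, model)
  b <- estimate_beta(series, zero, model, lag = 0L)
  structure(list(alpha_hat = a$par, beta_hat = b$par, rho_used = zero,
                 rho_estimated = FALSE,
                 h1_value = a$value, h2_value = b$value,
                 optimiser_info = list(alpha = a[c("method", "n_starts", "n_converged", "boundary")],
                                       beta = b[c("method", "n_starts", "n_converged", "boundary")]),
                 boundary_rho = FALSE, method = "lga"),
            class = "param_estimate")
}

#' @export
print.param_estimate <- function(x, ...) {
  cat(sprintf("<param_estimate> method = %s\n", x$method))
  cat("  rho_used:  ", paste(signif(x$rho_used, 5), collapse = ", "),
      if (x$rho_estimated) " (estimated)" else " (known)", "\n", sep = "")
  cat("  alpha_hat: ", paste(signif(x$alpha_hat, 5), collapse = ", "), "\n", sep = "")
  cat("  beta_hat:  ", paste(signif(x$beta_hat, 5), collapse = ", "), "\n", sep = "")
  cat(sprintf("  contrasts: H1 = %.6g, H2 = %.6g\n", x$h1_value, x$h2_value))
  invisible(x)
}
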