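# Study-design constants of the simulation experiments: a 1-D OU process
# (alpha = 3, beta = (-2, 1)) and a 2-D OU system sampled n = 1e5 times at
# h_n = 10^(-10/3), refined m = 2 decades for the convolution-by-summation.
design_1d <- function() {
  list(model = ou_preset_1d(), alpha = 3, beta = c(-2, 1),
       n = 1e5, h_n = 10^(-10 / 3), m = 2)
}

design_2d <- function() {
  list(model = ou_preset_2d(), alpha = c(2, 0, 3),
       beta = c(-2, -0.4, 0, 0.1, -3, 5),
       n = 1e5, h_n = 10^(-10 / 3), m = 2)
}

#' Run replicated simulation-estimation experiments
#'
#' Simulates `n_reps` independent convolutionally observed paths of a preset
#' OU design (seeded `base_seed + r` for replicate `r`), and on each runs the
#' smoothing-parameter estimator, the smoothness test, and (optionally) the
#' convolution-corrected and naive parameter fits. Deterministic given
#' `base_seed`.
#'
#' @param rho_star true smoothing parameter (scalar for `design = "ou1d"`,
#'   2-vector for `"ou2d"`).
#' @param n_reps number of replicates.
#' @param design `"ou1d"` or `"ou2d"`.
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`.
#' @param fit_params also run [fit_diffusion()] (plug-in rho) and [lga_fit()].
#' @param n,h_n,m design overrides (defaults are the preset study conditions).
#' @param rho_bar admissible upper bound for the smoothing parameter.
#' @return data.frame, one row per replicate, with per-axis columns `ratio`,
#'   `rho_hat`, `T` and, if `fit_params`, the fitted `alpha`, `beta` for both
#'   methods; carries the design as attributes.
#' @export
run_replicates <- function(rho_star, n_reps = 200, design = c("ou1d", "ou2d"),
                           base_seed = 1, fit_params = FALSE,
                           n = NULL, h_n = NULL, m = NULL, rho_bar = 100) {
  design <- match.arg(design)
  dsg <- if (design == "ou1d") design_1d() else design_2d()
  if (!is.null(n)) dsg$n <- n
  if (!is.null(h_n)) dsg$h_n <- h_n
  if (!is.null(m)) dsg$m <- m
  d <- dsg$model$d
  rho_star <- rep_len(as.numeric(rho_star), d)
  if (n_reps < 1) fail_validation("n_reps must be at least 1")
  rows <- vector("list", n_reps)
  n_fail <- 0
  for (r in seq_len(n_reps)) {
    row <- tryCatch(
      one_replicate(dsg, rho_star, seed = base_seed + r, fit_params = fit_params,
                    rho_bar = rho_bar),
      error = function(e) {
        message(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(row)) n_fail <- n_fail + 1 else rows[[r]] <- row
  }
  if (n_fail > max(1, 0.01 * n_reps))
    fail_numeric(n_fail, " of ", n_reps, " replicates failed")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- as.data.frame(out)
  attr(out, "rho_star") <- rho_star
  attr(out, "design") <- design
  attr(out, "truth") <- list(alpha = dsg$alpha, beta = dsg$beta, rho = rho_star)
  out
}

one_replicate <- function(dsg, rho_star, seed, fit_params, rho_bar) {
  cfg <- sim_config(n = dsg$n, h_n = dsg$h_n, m = dsg$m, x0 = 0, seed = seed)
  series <- simulate_convobs(dsg$model, dsg$alpha, dsg$beta, rho_star, cfg)
  est <- estimate_rho(series, rho_bar = rho_bar)
  tst <- smoothness_test(series)
  d <- series$d
  ax <- if (d == 1) "" else paste0("_", seq_len(d))
  row <- c(
    stats::setNames(est$ratio, paste0("ratio", ax)),
    stats::setNames(est$rho_hat, paste0("rho_hat", ax)),
    stats::setNames(tst$statistic, paste0("T", ax))
  )
  if (fit_params) {
    fc <- fit_diffusion(series, dsg$model, rho_bar = rho_bar)
    fl <- lga_fit(series, dsg$model)
    row <- c(row,
      stats::setNames(fc$alpha_hat, paste0("alpha_hat_", seq_along(fc$alpha_hat))),
      stats::setNames(fc$beta_hat, paste0("beta_hat_", seq_along(fc$beta_hat))),
      stats::setNames(fl$alpha_hat, paste0("lga_alpha_", seq_along(fl$alpha_hat))),
      stats::setNames(fl$beta_hat, paste0("lga_beta_", seq_along(fl$beta_hat))))
  }
  t(row)
}

#' Summarise replicate results against the design truth
#'
#' Empirical means, RMSEs and Monte-Carlo standard errors for every estimate
#' column, plus lower-tail rejection frequencies of the smoothness test at the
#' conventional levels.
#'
#' @param reps data.frame from [run_replicates()].
#' @param levels significance levels for the rejection-frequency table.
#' @return object of class `replication_summary`: list of data.frames
#'   `estimates` (columns: quantity, truth, mean, rmse, mc_se) and
#'   `rejections` (columns: axis, level, frequency, mc_se), plus `n_reps`.
#' @export
summarise_replicates <- function(reps, levels = c(0.10, 0.05, 0.025, 0.01, 0.001)) {
  truth <- attr(reps, "truth")
  nr <- nrow(reps)
  truth_of <- function(nm) {
    if (startsWith(nm, "rho_hat")) {
      i <- sub("^rho_hat_?", "", nm)
      truth$rho[if (i == "") 1 else as.integer(i)]
    } else if (startsWith(nm, "alpha_hat_") || startsWith(nm, "lga_alpha_")) {
      truth$alpha[as.integer(sub("^.*_", "", nm))]
    } else if (startsWith(nm, "beta_hat_") || startsWith(nm, "lga_beta_")) {
      truth$beta[as.integer(sub("^.*_", "", nm))]
    } else NA_real_
  }
  est_cols <- grep("^(rho_hat|alpha_hat|beta_hat|lga_alpha|lga_beta)", names(reps), value = TRUE)
  estimates <- do.call(rbind, lapply(est_cols, function(nm) {
    v <- reps[[nm]]
    tv <- truth_of(nm)
    data.frame(quantity = nm, truth = tv, mean = mean(v),
               rmse = sqrt(mean((v - tv)^2)), mc_se = stats::sd(v) / sqrt(nr))
  }))
  t_cols <- grep("^T(_|$)", names(reps), value = TRUE)
  rejections <- do.call(rbind, lapply(t_cols, function(nm) {
    do.call(rbind, lapply(levels, function(lv) {
      f <- mean(reps[[nm]] < qnorm(lv))
      data.frame(axis = nm, level = lv, frequency = f,
                 mc_se = sqrt(f * (1 - f) / nr))
    }))
  }))
  structure(list(estimates = estimates, rejections = rejections, n_reps = nr,
                 design = attr(reps, "design"), rho_star = attr(reps, "rho_star")),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("<replication_summary> design = %s, rho_star = (%s), %d replicates\n",
              x$design, paste(signif(x$rho_star, 4), collapse = ", "), x$n_reps))
  cat("estimates:\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  cat("smoothness-test rejection frequencies (lower tail):\n")
  print(x$rejections, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Scripted replication experiments
#'
#' One call per experiment family: smoothing-parameter recovery over a set of
#' true values (`"rho-small"`, `"rho-large"`), size and power of the
#' smoothness test (`"test"`), corrected-vs-naive parameter estimation
#' (`"theta-small"`), and the bivariate design (`"bivariate"`). Each runs
#' [run_replicates()] per `rho` value and returns the per-`rho` summaries.
#'
#' @param experiment experiment id.
#' @param rho_values true smoothing parameters to sweep (`NULL` = the
#'   experiment's default set, reduced to a practical sweep).
#' @param n_reps replicates per `rho` (default 200).
#' @param base_seed integer seed base; the sweep over `rho` uses disjoint seed
#'   blocks.
#' @param fit_params override whether parameter fits are run (default depends
#'   on the experiment).
#' @return named list of `replication_summary`, one per `rho` value.
#' @export
replicate_experiment <- function(experiment = c("rho-small", "test", "theta-small",
                                                "rho-large", "bivariate"),
                                 rho_values = NULL, n_reps = 200, base_seed = 1,
                                 fit_params = NULL) {
  experiment <- match.arg(experiment)
  defaults <- list(
    "rho-small"  = list(rho = c(0, 0.5, 0.9), design = "ou1d", fit = FALSE),
    "test"       = list(rho = c(0, 0.2), design = "ou1d", fit = FALSE),
    "theta-small" = list(rho = c(0, 0.5, 1), design = "ou1d", fit = TRUE),
    "rho-large"  = list(rho = 10, design = "ou1d", fit = TRUE),
    "bivariate"  = list(rho = list(c(2, 4)), design = "ou2d", fit = TRUE)
  )[[experiment]]
  if (is.null(rho_values)) rho_values <- defaults$rho
  if (!is.list(rho_values)) rho_values <- as.list(rho_values)
  if (is.null(fit_params)) fit_params <- defaults$fit
  out <- list()
  for (i in seq_along(rho_values)) {
    rho <- rho_values[[i]]
    reps <- run_replicates(rho, n_reps = n_reps, design = defaults$design,
                           base_seed = base_seed + (i - 1) * n_reps,
                           fit_params = fit_params)
    out[[paste0("rho=", paste(rho, collapse = ","))]] <- summarise_replicates(reps)
  }
  out
}
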