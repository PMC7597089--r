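sim_small_1d <- function(rho, n = 4e3, seed = 60) {
  cfg <- sim_config(n = n, h_n = 0.002, m = 2, seed = seed)
  simulate_convobs(ou_preset_1d(), 3, c(-2, 1), rho, cfg)
}

test_that("diffusion contrast is non-positive and reduces to the direct contrast at rho 0", {
  s <- sim_small_1d(0.5)
  m <- ou_preset_1d()
  for (a in c(0.5, 3, 8)) expect_lte(h1_objective(s, a, 0.5, m), 0)
  # rho = 0: the target is A itself, so the contrast equals the naive one
  dif <- diff(s$values)
  direct <- -sum((dif[, 1]^2 / s$h_n - 9)^2)
  expect_equal(h1_objective(s, 3, 0, m), direct, tolerance = 1e-10)
  # constant-diffusion sufficient-statistic path equals the generic loop
  m_generic <- m
  m_generic$diffusion_constant <- FALSE
  s_short <- convobs_series(s$values[1:201, , drop = FALSE], s$h_n)
  expect_equal(h1_objective(s_short, 2.5, 0.5, m),
               h1_objective(s_short, 2.5, 0.5, m_generic), tolerance = 1e-10)
  expect_error(h1_objective(s, 20, 0.5, m), class = "convodiff_validation_error")
})

test_that("drift contrast uses the lagged state and ignores beta when drift is zero", {
  s <- sim_small_1d(2.3)
  m <- ou_preset_1d()
  expect_lte(h2_objective(s, c(-2, 1), 2.3, m), 0)
  # lag: ceil(max rho) + 1
  expect_identical(convodiff:::h2_lag(2.3), 4L)
  expect_identical(convodiff:::h2_lag(c(0, 0)), 1L)
  # zero-drift model: objective is independent of beta
  mz <- zero_drift_model()
  expect_equal(h2_objective(s, 0.3, 0, mz), h2_objective(s, -0.9, 0, mz))
  expect_equal(h2_objective(s, 0.3, 0, mz), -sum(diff(s$values)[-1]^2) / s$h_n)
  expect_error(h2_objective(s, c(-2, 1), 0.5, m, lag = s$n),
               class = "convodiff_validation_error")
})

test_that("closed-form fast paths equal the generic optimiser", {
  s <- sim_small_1d(1)
  m <- ou_preset_1d()
  qv <- compute_qv_stats(s)
  # alpha at rho = 0: exactly sqrt(full QV)
  a_cf <- estimate_alpha(s, 0, m)
  expect_identical(a_cf$method, "closed_form")
  expect_equal(a_cf$par, sqrt(qv$full_qv[1]), tolerance = 1e-14)
  a_opt <- estimate_alpha(s, 0, m, use_closed_form = FALSE)
  expect_equal(a_opt$par, a_cf$par, tolerance = 1e-8)
  # and under a correction for the estimated window
  a_cf1 <- estimate_alpha(s, 1, m)
  a_opt1 <- estimate_alpha(s, 1, m, use_closed_form = FALSE)
  expect_equal(a_cf1$par, a_opt1$par, tolerance = 1e-8)
  expect_equal(a_cf1$par, sqrt(qv$full_qv[1] / fG(1, 1)), tolerance = 1e-14)
  # beta: least squares vs bounded multi-start
  b_ls <- estimate_beta(s, 1, m)
  expect_identical(b_ls$method, "least_squares")
  b_opt <- estimate_beta(s, 1, m, use_closed_form = FALSE)
  expect_equal(b_ls$par, b_opt$par, tolerance = 1e-6)
})

test_that("noiseless drift is recovered exactly by the one-lag contrast", {
  # deterministic recursion X_{k+1} = X_k + h (b1 X_k + b2)
  h <- 0.01
  x <- numeric(201)
  x[1] <- 2
  for (k in 1:200) x[k + 1] <- x[k] + h * (-1.5 * x[k] + 0.8)
  s <- convobs_series(x, h)
  b <- estimate_beta(s, 0, ou_preset_1d(), lag = 0L)
  expect_equal(b$par, c(-1.5, 0.8), tolerance = 1e-9)
})

test_that("plug-in fit and naive fit behave coherently on direct observations", {
  s <- sim_small_1d(0)
  m <- ou_preset_1d()
  f <- fit_diffusion(s, m)
  l <- lga_fit(s, m)
  # identical alpha objective at rho = 0, up to the rho estimate's perturbation
  f0 <- fit_diffusion(s, m, rho = 0)
  expect_identical(l$alpha_hat, f0$alpha_hat)
  expect_lte(f$h1_value, 0)
  expect_lte(f$h2_value, 0)
  expect_s3_class(f, "param_estimate")
  expect_identical(f$method, "convobs")
  expect_identical(l$method, "lga")
  expect_true(f$rho_estimated)
  expect_false(f0$rho_estimated)
  expect_equal(f$alpha_hat, 3, tolerance = 0.1)
})

test_that("bivariate diffusion parameters are recovered on a moderate sample", {
  m <- ou_preset_2d()
  cfg <- sim_config(n = 2e4, h_n = 0.002, m = 2, seed = 61)
  s <- simulate_convobs(m, c(2, 0, 3), c(-2, -0.4, 0, 0.1, -3, 5), c(2, 4), cfg)
  f <- fit_diffusion(s, m, rho = c(2, 4))
  expect_equal(f$alpha_hat, c(2, 0, 3), tolerance = 0.1)
  expect_false(f$boundary_rho)
  expect_identical(f$optimiser_info$alpha$method, "multi_start")
})
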