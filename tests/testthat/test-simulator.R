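test_that("Euler-Maruyama reproduces degenerate and deterministic dynamics", {
  # zero drift, zero diffusion: constant path
  m <- ode_model()
  cfg <- sim_config(n = 50, h_n = 0.01, m = 1, x0 = 2.5, seed = 1)
  p <- euler_maruyama(m, alpha = 0, beta = 0, cfg)
  expect_true(all(p == 2.5))
  # noiseless linear drift follows the exponential flow to O(h_sim)
  cfg <- sim_config(n = 1000, h_n = 1e-3, m = 2, x0 = 1, seed = 1)  # h_sim = 1e-5
  p <- euler_maruyama(m, alpha = 0, beta = -2, cfg, burn_in_steps = 0L)
  tt <- (0:(1000 * 100)) * cfg$h_sim
  expect_lt(max(abs(p[, 1] - exp(-2 * tt)) / exp(-2 * tt)), 1e-3)
})

test_that("long-run variance of a simulated OU process matches alpha^2 / (2|beta1|)", {
  m <- ou_preset_1d()
  cfg <- sim_config(n = 2e4, h_n = 0.01, m = 1, seed = 77)  # T = 200
  s <- simulate_convobs(m, alpha = 3, beta = c(-2, 0), rho = 0, cfg)
  v <- mean(s$values[, 1]^2)
  expect_equal(v, 9 / 4, tolerance = 0.2)  # ~3 Monte-Carlo SEs at T = 200
})

test_that("compiled and pure-R simulators draw the same path from one seed", {
  m1 <- ou_preset_1d()
  m2 <- m1
  m2$linear <- NULL  # force the generic loop
  cfg <- sim_config(n = 200, h_n = 0.01, m = 1, seed = 31)
  p1 <- euler_maruyama(m1, 3, c(-2, 1), cfg)
  p2 <- euler_maruyama(m2, 3, c(-2, 1), cfg)
  expect_equal(p1, p2, tolerance = 1e-12)
  # fused simulate+convolve equals the two-stage pipeline exactly
  burn <- convodiff:::resolve_burn_in(cfg, 1.5)
  s1 <- simulate_convobs(m1, 3, c(-2, 1), 1.5, cfg)
  p <- euler_maruyama(m1, 3, c(-2, 1), cfg, burn_in_steps = burn)
  s2 <- convolve_observations(p, cfg, 1.5, burn_in_steps = burn)
  expect_identical(s1$values, s2$values)
})

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  m <- ou_preset_1d()
  cfg <- sim_config(n = 500, h_n = 0.01, m = 1, seed = 123)
  s1 <- simulate_convobs(m, 3, c(-2, 1), 0.7, cfg)
  s2 <- simulate_convobs(m, 3, c(-2, 1), 0.7, cfg)
  expect_identical(s1$values, s2$values)
  cfg2 <- sim_config(n = 500, h_n = 0.01, m = 1, seed = 124)
  s3 <- simulate_convobs(m, 3, c(-2, 1), 0.7, cfg2)
  expect_false(identical(s1$values, s3$values))
})

test_that("convolution windows average the fine path as specified", {
  cfg <- sim_config(n = 10, h_n = 0.1, m = 2, seed = 1)
  stride <- 100
  burn <- convodiff:::resolve_burn_in(cfg, 1)   # (ceil(1)+1) * 100
  # deterministic ramp X_t = t on the fine grid, starting at -burn * h_sim
  tt <- ((-burn):(10 * stride)) * cfg$h_sim
  fine <- matrix(tt, ncol = 1)
  s <- convolve_observations(fine, cfg, rho = 1, burn_in_steps = burn)
  expected <- (0:10) * cfg$h_n - (cfg$h_n / 2) * (1 - 1 / stride)
  expect_equal(s$values[, 1], expected, tolerance = 1e-12)
  # rho = 0: exact subsampling of the latent path
  s0 <- convolve_observations(fine, cfg, rho = 0, burn_in_steps = burn)
  expect_identical(s0$values[, 1], fine[burn + 1 + (0:10) * stride, 1])
  # constant path stays constant under any window
  sc <- convolve_observations(matrix(3.5, nrow(fine), 1), cfg, rho = 1.7,
                              burn_in_steps = burn)
  expect_true(all(sc$values == 3.5))
  # a window longer than the burn-in is refused
  expect_error(convolve_observations(fine, cfg, rho = 5, burn_in_steps = burn),
               "burn-in")
})

test_that("observed increment variance matches the kernel deflation factor", {
  # driftless unit-coefficient model: full QV / A -> fG(rho, rho)
  m <- brownian_model()
  cfg <- sim_config(n = 2e4, h_n = 0.01, m = 2, seed = 5)
  for (rho in c(0.5, 1.5)) {
    s <- simulate_convobs(m, alpha = 1, beta = 0, rho = rho, cfg)
    qv <- compute_qv_stats(s)
    expect_equal(qv$full_qv[1], fG(rho, rho), tolerance = 0.05)
    expect_equal(qv$reduced_qv[1], qv_limit_reduced(rho), tolerance = 0.05)
  }
})

test_that("series files round-trip exactly through delimited text", {
  m <- ou_preset_1d()
  cfg <- sim_config(n = 100, h_n = 0.01, m = 1, seed = 2)
  s <- simulate_convobs(m, 3, c(-2, 1), 0.3, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_identical(s2$values, s$values)
  expect_equal(s2$h_n, s$h_n, tolerance = 1e-12)
  s3 <- read_series(path, h_n = 0.01)
  expect_identical(s3$values, s$values)
  # malformed inputs are rejected
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_series(empty), class = "convodiff_validation_error")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x1", "0,1", "0.1,abc"), bad)
  expect_error(read_series(bad), class = "convodiff_validation_error")
  expect_error(read_series("/nonexistent/file.csv"), class = "convodiff_validation_error")
  # dimension propagation for wide (EEG-style) tables
  wide <- withr::local_tempfile(fileext = ".csv")
  M <- matrix(rnorm(20 * 15), 20, 15)
  write_series(convobs_series(M, h_n = 1 / 2560), wide)
  expect_equal(read_series(wide)$d, 15)
})
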