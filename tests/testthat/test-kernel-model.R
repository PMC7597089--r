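test_that("fG matches its closed-form anchor values", {
  expect_identical(fG(0, 0), 1)
  expect_equal(fG(1, 1), 2 / 3)
  expect_equal(fG(2, 2), 5 / 12)          # 1/rho - 1/(3 rho^2) at rho = 2
  expect_equal(fG(0, 0.5), 0.75)          # 1 - v/2 branch
  expect_equal(fG(0, 3), 1 / 6)           # 1/(2v) branch
  expect_equal(fG(2, 4), 11 / 48)         # disjoint windows (6u-1)/(6uv)
  expect_error(fG(-0.1, 0), class = "convodiff_validation_error")
  expect_error(fG(0, 5, rho_bar = 3), class = "convodiff_validation_error")
})

test_that("fG is symmetric and continuous across every branch seam", {
  g <- seq(0, 3, by = 0.25)
  for (s in g) for (t in g) expect_equal(fG(s, t), fG(t, s), tolerance = 1e-14)
  eps <- 1e-9
  # seams: an argument crossing 0 or 1, and the window-overlap edge v = u + 1
  seams <- rbind(
    cbind(0 + eps, g), cbind(1 - eps, g), cbind(1 + eps, g),
    cbind(g, pmin(g + 1 - eps, 100)), cbind(g, g + 1 + eps)
  )
  base <- rbind(cbind(0, g), cbind(1, g), cbind(1, g), cbind(g, g + 1), cbind(g, g + 1))
  for (i in seq_len(nrow(seams))) {
    expect_equal(fG(seams[i, 1], seams[i, 2]), fG(base[i, 1], base[i, 2]),
                 tolerance = 1e-7)
  }
})

test_that("quadratic-variation limits are continuous and sit on the fG diagonal", {
  expect_identical(qv_limit_full(0), 1)
  expect_equal(qv_limit_full(1), 2 / 3)
  expect_equal(qv_limit_full(10), 1 / 10 - 1 / 300)
  expect_identical(qv_limit_reduced(0), 1)
  expect_equal(qv_limit_reduced(2), 2 / 3)
  expect_equal(qv_limit_reduced(3), 14 / 27)
  r <- seq(0.05, 5, by = 0.05)
  expect_equal(qv_limit_full(r), fG(r, r))
  # seam continuity
  expect_equal(qv_limit_full(1 - 1e-10), qv_limit_full(1 + 1e-10), tolerance = 1e-9)
  expect_equal(qv_limit_reduced(2 - 1e-10), qv_limit_reduced(2 + 1e-10), tolerance = 1e-9)
  expect_error(qv_limit_full(-1), class = "convodiff_validation_error")
})

test_that("ratio function is the limit quotient, strictly decreasing, with exact inverse", {
  expect_identical(ratio_R(0), 1)
  expect_equal(ratio_R(1), 4 / 5)
  expect_equal(ratio_R(2), 5 / 8)
  expect_equal(ratio_R(3), 4 / 7)
  r <- seq(0, 100, by = 0.125)
  expect_equal(ratio_R(r), qv_limit_full(r) / qv_limit_reduced(r), tolerance = 1e-12)
  expect_true(all(diff(ratio_R(r)) < 0))
  # inverse: branch boundaries and round trips on all three branches
  expect_equal(ratio_R_inverse(4 / 5), 1)
  expect_equal(ratio_R_inverse(5 / 8), 2)
  y <- ratio_R_inverse(0.7)
  expect_true(y > 1 && y < 2)
  expect_equal(ratio_R(y), 0.7, tolerance = 1e-10)
  rr <- seq(0.05, 99.5, by = 0.41)
  expect_equal(ratio_R_inverse(ratio_R(rr)), rr, tolerance = 1e-10)
  expect_error(ratio_R_inverse(1.0), class = "convodiff_validation_error")
  expect_error(ratio_R_inverse(0.49), class = "convodiff_validation_error")
})

test_that("G matrix scales the infinitesimal covariance and stays PSD", {
  expect_equal(G_matrix(diag(2), c(0, 0)), diag(2))
  expect_equal(G_matrix(matrix(9, 1, 1), 1), matrix(6, 1, 1))
  A <- matrix(c(2, 0, 0, 3), 2, 2)^2  # a = diag(2, 3) -> A = diag(4, 9)
  G <- G_matrix(A, c(2, 4))
  expect_equal(diag(G), c(4 * (5 / 12), 9 * (1 / 4 - 1 / 48)))
  expect_equal(G[1, 2], 0)
  set.seed(11)
  for (i in 1:20) {
    d <- sample(2:4, 1)
    M <- matrix(rnorm(d * d), d)
    A <- crossprod(M)
    rho <- runif(d, 0, 6)
    ev <- eigen(G_matrix(A, rho), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_error(G_matrix(matrix(1, 2, 3), c(0, 0)), class = "convodiff_validation_error")
})

test_that("quadrature oracle confirms the closed forms", {
  expect_identical(covariance_oracle(0, 0), 1)
  expect_equal(covariance_oracle(1, 1, n_grid = 2000), 2 / 3, tolerance = 1e-4)
  expect_equal(covariance_oracle(0.3, 1.7, n_grid = 2000), fG(0.3, 1.7), tolerance = 1e-4)
  expect_equal(covariance_oracle(0, 0.5, n_grid = 2000), 0.75, tolerance = 1e-4)
  # two-step increments recover the reduced-QV limit on the diagonal
  for (r in c(0.5, 1.5, 3)) {
    expect_equal(covariance_oracle(r, r, n_grid = 1500, step = 2),
                 qv_limit_reduced(r), tolerance = 1e-3)
  }
})
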