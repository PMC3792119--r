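test_that("regressor matrix realises C(x) %*% vec(A) = A %*% x", {
  expect_equal(build_regressor(c(1, 2), intercept = FALSE),
               matrix(c(1, 0, 0, 1, 2, 0, 0, 2), 2, 4))
  expect_equal(build_regressor(c(1, 2), intercept = TRUE),
               matrix(c(1, 0, 0, 1, 2, 0, 0, 2, 1, 0, 0, 1), 2, 6))
  set.seed(1)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    x <- rnorm(3)
    expect_equal(as.numeric(build_regressor(x, FALSE) %*% as.numeric(A)),
                 as.numeric(A %*% x), tolerance = 1e-12)
    b <- rnorm(3)
    expect_equal(
      as.numeric(build_regressor(x, TRUE) %*% c(as.numeric(A), b)),
      as.numeric(A %*% x + b), tolerance = 1e-12)
  }
  expect_error(build_regressor(numeric(0)), "non-empty")
})

test_that("scalar RLS update matches the one-step closed form", {
  st <- parameter_state(1, intercept = FALSE, p0 = 1e6)
  u <- rls_update(st, 1, 0.5, matrix(1, 1, 1))
  expect_equal(u$innovation$e, 0.5)
  expect_equal(u$innovation$S[1, 1], 1e6 + 1)
  expect_equal(u$state$theta_hat, 0.5 * 1e6 / (1e6 + 1), tolerance = 1e-12)
  expect_equal(u$innovation$z, 0.5 / sqrt(1e6 + 1))
})

test_that("an exactly predicted sample leaves the estimate unchanged", {
  st <- parameter_state(2, intercept = FALSE, p0 = 10)
  st$theta_hat <- c(0.5, 0, 0, 0.25)          # A = diag(0.5, 0.25)
  x <- c(2, 4)
  u <- rls_update(st, x, c(1, 1), diag(0.1, 2))
  expect_equal(u$innovation$e, c(0, 0))
  expect_equal(u$state$theta_hat, st$theta_hat)
})

test_that("RLS converges to the generating coefficient on noiseless data", {
  xs <- c(1, 0.5, 0.25, 0.125)
  st <- parameter_state(1, intercept = FALSE, p0 = 1e6)
  for (t in 2:4) st <- rls_update(st, xs[t - 1], xs[t], matrix(1, 1, 1))$state
  expect_equal(st$theta_hat, 0.5, tolerance = 1e-5)
})

test_that("whitening inverts the lower Cholesky factor", {
  expect_equal(normalize_innovation(c(0, 0), diag(2)), c(0, 0))
  expect_equal(normalize_innovation(2, matrix(4, 1, 1)), 1)
  expect_equal(normalize_innovation(c(2, 4), diag(c(2, 8))),
               c(sqrt(2), sqrt(2)))
  # z'z = e' S^-1 e for a dense PD matrix
  set.seed(2)
  S <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  e <- rnorm(3)
  z <- normalize_innovation(e, S)
  expect_equal(sum(z^2), as.numeric(t(e) %*% solve(S) %*% e),
               tolerance = 1e-8)
  expect_error(normalize_innovation(c(1, 1), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("Q statistic sums squared components with dof = n*m", {
  expect_equal(q_statistic(rep(list(rep(0, 3)), 5)), list(Q = 0, dof = 15L))
  expect_equal(q_statistic(list(c(1, 0), c(0, 1))), list(Q = 2, dof = 4L))
  expect_error(q_statistic(list()), "non-empty")
  # null calibration of the statistic itself: standard-normal components
  set.seed(4)
  Q <- replicate(10000, q_statistic(matrix(rnorm(8), 2, 4))$Q)
  expect_gt(stats::ks.test(Q, stats::pchisq, df = 8)$p.value, 0.01)
})

test_that("chi-square thresholds match tabulated quantiles and order", {
  expect_equal(chi2_threshold(0.05, 1), 3.841, tolerance = 1e-3)
  expect_equal(chi2_threshold(0.05, 10), 18.307, tolerance = 1e-3)
  expect_true(all(diff(chi2_threshold(0.05, 1:50)) > 0))
  expect_error(chi2_threshold(1.2, 3), "alpha")
})

test_that("P stays symmetric PSD across many random updates", {
  set.seed(5)
  st <- parameter_state(2, intercept = TRUE, p0 = 100)
  for (i in 1:1000) {
    st <- rls_update(st, rnorm(2), rnorm(2), diag(0.5, 2))$state
    expect_equal(st$P, t(st$P))
  }
  expect_gte(min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("whitened innovations are jointly rescale-invariant", {
  # x -> c x, Sigma -> c^2 Sigma with p0 unchanged leaves every z the same:
  # the AR coefficients are dimensionless, so their prior need not scale
  sim <- single_regime_series(2, 40, seed = 6, noise_mean = 1,
                              noise_var = 0.3)
  cc <- 7.5
  scaled <- expression_series(cc * sim$series$values, sim$series$gene_ids)
  base <- collect_innovations(sim$series, diag(0.3, 2), p0 = 1e4,
                              intercept = FALSE)
  reran <- collect_innovations(scaled, cc^2 * diag(0.3, 2), p0 = 1e4,
                               intercept = FALSE)
  expect_equal(base$Z, reran$Z, tolerance = 1e-9)
})

test_that("noise covariance is near zero on noiseless data", {
  A <- make_random_sparse_stable_matrix(3, 4, seed = 8, radius_cap = 0.8)
  m <- sar_model(list(A), integer(0), rep(1, 3), matrix(0, 3, 3))
  es <- simulate_sar(m, 60L, c(3, 1, 2), seed = 1)
  ne <- estimate_noise_covariance(es, lambda = 0.98, p0 = 1e6, burn_in = 5)
  expect_lt(max(abs(ne$sigma_hat)), 1e-6)
})

test_that("forgetting-factor RLS recovers the scalar residual variance", {
  m <- sar_model(list(matrix(0.5, 1, 1)), integer(0), 0, matrix(0.25, 1, 1))
  ests <- vapply(1:5, function(s) {
    es <- simulate_sar(m, 500L, 0, seed = s)
    estimate_noise_covariance(es, lambda = 0.98, p0 = 1e6, burn_in = 5,
                              intercept = FALSE)$sigma_hat[1, 1]
  }, numeric(1))
  expect_true(all(ests >= 0.18 & ests <= 0.32))
})

test_that("noise estimate centres residuals so a mean offset does not leak", {
  # zero-mean model fit (no intercept) on mean-2 noise: covariance still ~ Sigma
  sim <- single_regime_series(2, 500, seed = 13, noise_mean = 2,
                              noise_var = 0.5, n_edges = 2, radius_cap = 0.6)
  ne <- estimate_noise_covariance(sim$series, intercept = FALSE)
  expect_lt(norm(ne$sigma_hat - diag(0.5, 2), "F") / norm(diag(0.5, 2), "F"),
            0.5)
  expect_error(estimate_noise_covariance(
    expression_series(matrix(rnorm(12), 2, 6)), burn_in = 5), "too short")
  expect_error(estimate_noise_covariance(
    expression_series(matrix(rnorm(16), 2, 8)), burn_in = 5), "residuals")
})

test_that("batch least squares recovers noiseless dynamics and min-norm", {
  A <- make_random_sparse_stable_matrix(3, 5, seed = 10, radius_cap = 0.9)
  m <- sar_model(list(A), integer(0), rep(0, 3), matrix(0, 3, 3))
  es <- simulate_sar(m, 30L, c(1, -2, 3), seed = 1)
  est <- batch_least_squares(es, intercept = FALSE)
  expect_equal(unname(est), A, tolerance = 1e-8)

  # single transition, underdetermined: prediction reproduces x_next exactly
  es2 <- expression_series(matrix(c(1, 2, 3, 4, 5, 6), 2, 3), c("a", "b"))
  est2 <- batch_least_squares(es2, t_start = 1, t_end = 2, intercept = FALSE)
  expect_equal(as.numeric(est2 %*% es2$values[, 1]),
               unname(es2$values[, 2]), tolerance = 1e-9)
})

test_that("diffuse RLS agrees with batch least squares", {
  sim <- single_regime_series(2, 40, seed = 12, noise_mean = 2,
                              noise_var = 0.5)
  got <- collect_innovations(sim$series, diag(0.5, 2), p0 = 1e8)
  rls_coef <- state_coefficients(got$state)
  batch <- batch_least_squares(sim$series, intercept = TRUE)
  expect_equal(rls_coef$A, unname(batch[, 1:2]), tolerance = 1e-4)
  expect_equal(rls_coef$offset, unname(batch[, 3]), tolerance = 1e-4)
})
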