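test_that("iota score handles the canonical orderings", {
  expect_equal(iota_score(c(1, 2, 3, 4), c(10, 20, 30, 40)), 1)
  expect_equal(iota_score(c(1, 2, 3, 4), c(40, 30, 20, 10)), 0)
  expect_equal(iota_score(c(3, 1, 2), c(5, 7, 9)), 1 / 3)
  expect_error(iota_score(1, 1), "at least 2")
  expect_error(iota_score(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("iota equals brute-force inversion counting on random series", {
  set.seed(21)
  for (i in 1:200) {
    M <- sample(3:12, 1)
    x <- rnorm(M)
    y <- if (i %% 3 == 0) sample(x) else rnorm(M)  # include tied values
    expect_equal(iota_score(x, y), iota_brute(x, y))
  }
})

test_that("iota is a rank statistic: invariant to increasing transforms", {
  set.seed(22)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(iota_score(exp(x), y), iota_score(x, y))
  expect_equal(iota_score(x, 3 * y + 10), iota_score(x, y))
  expect_equal(iota_score(qnorm(pnorm(x)), y^3 - y * 0), iota_score(x, y^3))
})

test_that("exact ties are not crossings", {
  expect_equal(iota_score(c(1, 2, 3), c(4, 4, 4)), 1)  # constant target
  expect_equal(iota_score(c(1, 2, 3, 4), c(1, 1, 2, 2)), 1)
})

test_that("iota network scores are bounded and zero on the diagonal", {
  set.seed(23)
  seg <- expression_series(matrix(rnorm(5 * 12), 5, 12))
  net <- score_network_iota(seg)
  expect_true(all(net$score >= 0 & net$score <= 1))
  expect_equal(unname(diag(net$score)), rep(0, 5))
  expect_equal(unname(net$score[1, 2]),
               iota_score(seg$values[1, ], seg$values[2, ]))
  # two co-monotone genes score 1 both ways
  seg2 <- expression_series(rbind(1:6, c(2, 4, 6, 8, 10, 12)))
  net2 <- score_network_iota(seg2)
  expect_equal(unname(net2$score), matrix(c(0, 1, 1, 0), 2, 2))
  # per-gene monotone transforms leave the whole matrix unchanged
  tseg <- expression_series(rbind(exp(seg$values[1:2, ]),
                                  seg$values[3:5, ] * 4 - 1))
  expect_equal(unname(score_network_iota(tseg)$score), unname(net$score))
})

test_that("coordinate descent solves the penalised objective", {
  set.seed(24)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- X %*% c(1, -2, 0, 0, 0.5) + rnorm(40, sd = 0.3)
  # zero penalty equals ordinary least squares
  a0 <- lasso_fit_gene(y, X, 0, intercept = TRUE)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(as.numeric(a0), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(attr(a0, "offset"), unname(ols[1]), tolerance = 1e-6)
  # the kill condition empties the model
  lam_max <- max(abs(crossprod(X, y - mean(y))))
  expect_equal(as.numeric(lasso_fit_gene(y, X, lam_max * 1.0001)), rep(0, 5))
  # objective matches the independent proximal-gradient oracle
  for (i in 1:20) {
    Xi <- matrix(rnorm(30 * 5), 30, 5)
    yi <- rnorm(30)
    pen <- runif(1, 0.1, 5)
    fit <- lasso_fit_gene(yi, Xi, pen, intercept = TRUE)
    expect_equal(lasso_objective(yi, Xi, as.numeric(fit),
                                 attr(fit, "offset"), pen),
                 fista_lasso(yi, Xi, pen)$obj, tolerance = 1e-6)
  }
  expect_error(lasso_fit_gene(y, X, -1), ">= 0")
})

test_that("lasso network recovers a strong sparse support exactly", {
  A <- matrix(0, 5, 5); A[2, 1] <- 0.8; A[4, 3] <- -0.7; A[5, 4] <- 0.6
  m <- sar_model(list(A), integer(0), rep(0, 5), diag(0.25, 5))
  for (s in 51:55) {
    es <- simulate_sar(m, 100L, rnorm(5), seed = s)
    net <- infer_network_lasso(es, penalty = 10, intercept = TRUE)
    expect_identical(unname(net$coefficients != 0), unname(A != 0))
    # signs of the recovered interactions match the generator
    expect_gt(net$coefficients[2, 1], 0)
    expect_lt(net$coefficients[4, 3], 0)
    # scores transpose coefficients: regulator rows to score rows
    expect_equal(unname(net$score), unname(t(abs(net$coefficients))))
  }
})

test_that("lasso rows are independent per-target problems", {
  set.seed(26)
  es <- expression_series(matrix(rnorm(4 * 30), 4, 30))
  net <- infer_network_lasso(es, penalty = 2)
  X <- t(es$values[, 1:29])
  for (g in 1:4) {
    row_fit <- lasso_fit_gene(es$values[g, 2:30], X, 2, intercept = TRUE)
    expect_equal(unname(net$coefficients[g, ]), as.numeric(row_fit),
                 tolerance = 1e-9)
  }
  # a huge penalty empties the network
  empty <- infer_network_lasso(es, penalty = 1e6)
  expect_equal(sum(empty$score), 0)
})

test_that("cross-validated penalty selection is seeded and sane", {
  sim <- single_regime_series(3, 40, seed = 27, noise_mean = 0,
                              noise_var = 0.25, radius_cap = 0.8)
  set.seed(1); net1 <- infer_network_lasso(sim$series, penalty = "cv")
  set.seed(1); net2 <- infer_network_lasso(sim$series, penalty = "cv")
  expect_identical(net1$penalty, net2$penalty)
  expect_gt(net1$penalty, 0)
})

test_that("auroc follows the Mann-Whitney pair count", {
  truth <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3)
  perfect <- truth * 0.9 + (1 - truth) * 0.1; diag(perfect) <- 0
  expect_equal(auroc(perfect, truth), 1)
  expect_equal(auroc(1 - perfect, truth), 0)
  set.seed(28)
  for (i in 1:25) {
    score <- matrix(runif(9), 3, 3)
    if (i %% 4 == 0) score <- round(score, 1)   # exercise ties
    expect_equal(auroc(score, truth), auroc_brute(score, truth))
  }
  # complement symmetry for tie-free scores
  score <- matrix(c(0, .11, .32, .53, 0, .75, .96, .17, 0), 3, 3)
  expect_equal(auroc(score, truth) + auroc(-score, truth), 1)
  expect_error(auroc(score, matrix(1, 3, 3) - diag(3) * 0), "positive and")
})

test_that("aupr integrates the precision-recall step curve", {
  truth <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3)
  perfect <- truth * 0.9 + (1 - truth) * 0.1; diag(perfect) <- 0
  expect_equal(aupr(perfect, truth), 1)
  # single true edge ranked last among 6 candidates: area = prevalence at
  # full recall only
  one <- matrix(0, 3, 3); one[2, 1] <- 1
  worst <- matrix(c(0, .1, .6, .5, 0, .4, .3, .2, 0), 3, 3)
  expect_equal(aupr(worst, one), 1 / 6)
  set.seed(29)
  for (i in 1:25) {
    score <- matrix(runif(9), 3, 3)
    if (i %% 4 == 0) score <- round(score, 1)
    expect_equal(aupr(score, truth), aupr_brute(score, truth))
  }
})

test_that("random scores give an AUPR near the edge prevalence", {
  set.seed(31)
  vals <- replicate(200, {
    truth <- matrix(rbinom(400, 1, 0.1), 20, 20); diag(truth) <- 0
    while (sum(truth) == 0) truth <- matrix(rbinom(400, 1, 0.1), 20, 20)
    aupr(matrix(runif(400), 20, 20), truth)
  })
  expect_lt(abs(mean(vals) - 0.10), 0.05)
})
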