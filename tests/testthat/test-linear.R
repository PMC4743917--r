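test_that("standardization centers, scales to squared norm n, and is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(0, 1, 0))
  y <- c(1, 1, 1)
  pr <- linear_problem(X, y)
  expect_equal(pr$X[, "a"], c(-sqrt(1.5), 0, sqrt(1.5)))
  expect_equal(colSums(pr$X^2), c(a = 3, b = 3))
  expect_equal(pr$y, c(0, 0, 0))
  # idempotence: standardizing a standardized problem changes nothing
  pr2 <- linear_problem(pr$X, pr$y)
  expect_equal(pr2$X, pr$X, tolerance = 1e-12)
  # zero-variance column is rejected by name
  expect_error(linear_problem(cbind(u = c(1, 1, 1), v = 1:3), 1:3), "u")
})

test_that("weighted ridge solves the penalized normal equations", {
  # hand-solved scalar case: beta = 2 / (2 + 2) = 0.5
  pr <- linear_problem(matrix(c(1, 1), 2, 1), c(0, 2), standardize = FALSE)
  expect_equal(weighted_ridge(pr, lambda = 2, weights = 1), 0.5)
  # zero weights with full-rank X: ordinary least squares
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4); y <- rnorm(10)
  pr <- linear_problem(X, y, standardize = FALSE)
  expect_equal(weighted_ridge(pr, 5, rep(0, 4)),
               unname(lm.fit(X, y)$coefficients), tolerance = 1e-10)
  # massive penalty shrinks towards zero
  b_big <- weighted_ridge(pr, 1e12, rep(1, 4))
  expect_lt(sqrt(sum(b_big^2)),
            1e-6 * sqrt(sum(lm.fit(X, y)$coefficients^2)))
  expect_error(weighted_ridge(pr, 1, rep(-1, 4)), "non-negative")
})

test_that("L0 penalty rescaling is lambda / 4", {
  expect_equal(l0_to_ar(log(50)), log(50) / 4)
  expect_equal(l0_to_ar(0), 0)
  expect_equal(l0_to_ar(2), 0.5)  # AIC
})

test_that("orthogonal-design AR limits match the closed form and the scalar map", {
  n <- 100
  ctrl <- ar_control()
  # retained coordinate: threshold 4*lambda*sigma2/n = 0.04 < 0.25
  expect_equal(orthogonal_fixed_point(0.5, n, 1, 1),
               (0.5 + sqrt(0.25 - 0.04)) / 2)
  expect_equal(orthogonal_fixed_point(0.5, n, 1, 1), 0.47913,
               tolerance = 1e-4)
  expect_equal(orthogonal_fixed_point(0.5, n, 1, 1),
               scalar_ar_limit(0.5, n, 1, 1), tolerance = 1e-6)
  # dropped coordinate
  expect_equal(orthogonal_fixed_point(0.15, n, 1, 1), 0)
  expect_equal(scalar_ar_limit(0.15, n, 1, 1), 0, tolerance = 1e-6)
  # boundary: double root beta_hat / 2
  lam_b <- 0.3^2 * n / 4
  expect_equal(orthogonal_fixed_point(0.3, n, 1, lam_b), 0.15)
  # no penalty: OLS unchanged
  expect_equal(orthogonal_fixed_point(c(-0.4, 0.2), n, 1, 0), c(-0.4, 0.2))

  # full matrix fit on an orthonormal design reproduces the per-coordinate limit
  X <- make_orthonormal_design(n, 4, seed = 11)
  bh <- c(0.5, 0.15, -0.7, 0.25)
  pr <- linear_problem(X, drop(X %*% bh), standardize = FALSE)
  fit <- ar_lm(pr, lambda = 1, ctrl)
  expect_equal(fit$state$beta, orthogonal_fixed_point(bh, n, 1, 1),
               tolerance = 1e-6)
  expect_equal(which(fit$support), c(1L, 3L, 4L))
})

test_that("AR iterates stay bounded and shrink on orthonormal designs", {
  n <- 80; p <- 6
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n, mean = X[, 1])
    pr <- linear_problem(X, y)
    fit <- ar_lm(pr, lambda = l0_to_ar(log(n)), keep_history = TRUE)
    ols <- lm.fit(pr$X, pr$y)$coefficients
    expect_lte(sqrt(sum(fit$state$beta^2)), sqrt(sum(ols^2)) + 1e-8)
  }
  # orthonormal: coordinate-wise |AR limit| <= |OLS|
  X <- make_orthonormal_design(n, p, seed = 5)
  bh <- c(0.8, -0.5, 0.3, 0.21, -0.1, 0)
  pr <- linear_problem(X, drop(X %*% bh), standardize = FALSE)
  fit <- suppressWarnings(ar_lm(pr, lambda = 1))
  expect_true(all(abs(fit$state$beta) <= abs(bh) + 1e-8))
})

test_that("coordinates absorbed at zero stay there", {
  set.seed(9)
  n <- 60; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.8)) + rnorm(n)
  fit <- suppressWarnings(
    ar_lm(linear_problem(X, y), lambda = l0_to_ar(log(n)),
          keep_history = TRUE))
  H <- fit$history
  for (j in seq_len(p)) {
    dropped_at <- which(H[, j] < 1e-4)
    if (length(dropped_at))
      expect_true(all(H[seq(min(dropped_at), nrow(H)), j] <= 0.5))
  }
})

test_that("non-convergence warns and returns the last state", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  expect_warning(
    fit <- ar_lm(linear_problem(X, y), lambda = 1,
                 ar_control(max_iter = 2L)),
    "did not converge")
  expect_false(fit$state$converged)
  expect_length(fit$state$beta, 5)
})

test_that("forced-in coordinates keep weight zero and are always selected", {
  set.seed(14)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)  # pure noise: nothing would be selected on merit
  ctrl <- ar_control(init_weights = c(0, 1, 1, 1))
  fit <- suppressWarnings(ar_lm(linear_problem(X, y), lambda = l0_to_ar(log(n)), ctrl))
  expect_identical(fit$state$weights[1], 0)
  expect_true(fit$support[1])
})

test_that("paths warm-start over increasing penalties down to an empty support", {
  set.seed(31)
  n <- 100; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1.2, -1, 0.9)) + rnorm(n)
  pr <- linear_problem(X, y)
  expect_error(ar_lm_path(pr, lambdas = c(2, 1)), "increasing")
  # a single-element grid reduces to ar_lm at that penalty
  single <- ar_lm_path(pr, lambdas = 5)
  solo <- suppressWarnings(ar_lm(pr, 5))
  expect_equal(single$fits[[1]]$support, solo$support)
  expect_equal(single$fits[[1]]$rss, solo$rss)
  # default grid: support empties at the top of the path
  path <- ar_lm_path(pr)
  expect_identical(tail(path$support_sizes, 1), 0L)
  expect_gte(path$support_sizes[1], 3L)
})

test_that("warm-started path fits match cold restarts on orthonormal designs", {
  n <- 100; p <- 6
  X <- make_orthonormal_design(n, p, seed = 8)
  bh <- c(0.9, -0.6, 0.4, 0.25, 0.1, 0)
  pr <- linear_problem(X, drop(X %*% bh), standardize = FALSE)
  path <- ar_lm_path(pr, lambdas = ar_lambda_grid(n, 1, 25))
  spec <- criterion("bic")
  for (i in c(5, 12, 20)) {
    warm <- evaluate_criterion(pr, path$fits[[i]]$support, spec)
    cold <- suppressWarnings(ar_lm(pr, path$lambdas[i]))
    cold_crit <- evaluate_criterion(pr, cold$support, spec)
    expect_equal(warm$criterion, cold_crit$criterion, tolerance = 1e-6)
  }
})

test_that("rank-deficient zero-penalty solves are ridge-stabilized with a warning", {
  set.seed(4)
  X <- matrix(rnorm(5 * 8), 5, 8)  # p > n
  y <- rnorm(5)
  expect_warning(ar_lm(linear_problem(X, y), lambda = 0), "rank-deficient")
})

test_that("variance plug-in uses full-model residuals or a refit", {
  set.seed(66)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1]) + rnorm(n, sd = 2)
  pr <- linear_problem(X, y)
  s2 <- estimate_sigma2(pr)
  expect_equal(s2, sum(lm.fit(pr$X, pr$y)$residuals^2) / (n - p))
  # p >= n requires an explicit support
  wide <- linear_problem(matrix(rnorm(10 * 12), 10, 12), rnorm(10))
  expect_error(estimate_sigma2(wide), "supply")
  s2w <- estimate_sigma2(wide, support = 1:2)
  expect_gt(s2w, 0)
})

test_that("random restarts never report a worse criterion than the default start", {
  set.seed(91)
  n <- 80; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:4] %*% c(0.6, -0.5, 0.45, 0.4)) + rnorm(n)
  pr <- linear_problem(X, y)
  spec <- criterion("bic")
  lam <- l0_to_ar(log(n))
  base <- suppressWarnings(ar_lm(pr, lam))
  base_crit <- evaluate_criterion(pr, base$support, spec)$criterion
  multi <- ar_lm_restarts(pr, lam, spec, restarts = 4, seed = 2)
  expect_lte(multi$criterion, base_crit + 1e-12)
  # determinism of the restart draws
  multi2 <- ar_lm_restarts(pr, lam, spec, restarts = 4, seed = 2)
  expect_equal(multi$criterion, multi2$criterion)
  expect_equal(multi$support, multi2$support)
})

test_that("at convergence the summed indicators approximate the support size", {
  set.seed(101)
  n <- 120; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:4] %*% c(1.2, -0.9, 0.8, 0.7)) + rnorm(n)
  fit <- suppressWarnings(ar_lm(linear_problem(X, y), l0_to_ar(log(n))))
  k <- sum(fit$support)
  beta_min <- min(abs(fit$state$beta[fit$support]))
  bound <- k * (1e-5 / beta_min)^2 + 1e-6
  expect_lt(abs(sum(fit$state$indicators) - k), max(bound, 1e-6))
})
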