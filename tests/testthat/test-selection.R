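test_that("criterion penalties follow the AIC/BIC/mBIC formulas", {
  expect_equal(adaridge:::criterion_penalty(criterion("aic"), 100, 10), 2)
  expect_equal(adaridge:::criterion_penalty(criterion("bic"), 100, 10), log(100))
  expect_equal(
    adaridge:::criterion_penalty(criterion("mbic", c = 4, p_total = 1000), 100, 10),
    log(100 * 1000^2 / 16))
  expect_equal(log(100 * 1000^2 / 16), 15.6481, tolerance = 1e-4)
  # p_total defaults to the problem's p
  expect_equal(adaridge:::criterion_penalty(criterion("mbic", c = 2), 50, 30),
               log(50 * 900 / 4))
})

test_that("criterion evaluation refits ML and is additive in the penalty", {
  set.seed(6)
  n <- 40; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1] * 2) + rnorm(n)
  pr <- linear_problem(X, y)
  spec <- criterion("bic")
  empty <- evaluate_criterion(pr, integer(0), spec)
  expect_equal(empty$criterion, sum(pr$y^2))  # RSS_null / sigma2, zero penalty
  m1 <- evaluate_criterion(pr, 1L, spec)
  m12 <- evaluate_criterion(pr, c(1L, 2L), spec)
  expect_equal(m12$criterion - m1$criterion,
               (m12$minus2loglik - m1$minus2loglik) + log(n))
  expect_error(evaluate_criterion(pr, seq_len(p + 1), spec))
  wide <- linear_problem(matrix(rnorm(20 * 25), 20, 25), rnorm(20))
  expect_error(evaluate_criterion(wide, 1:20, criterion("bic")), "smaller than n")
})

test_that("estimated-variance criterion uses n log(RSS/n)", {
  set.seed(61)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  pr <- linear_problem(X, y)
  f <- evaluate_criterion(pr, 1L, criterion("bic", variance = "estimated"))
  rss <- sum(lm.fit(pr$X[, 1, drop = FALSE], pr$y)$residuals^2)
  expect_equal(f$minus2loglik, 20 * log(rss / 20))
})

test_that("all-subset search equals brute-force refits and the orthonormal rule", {
  set.seed(17)
  n <- 50; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1, -0.8, 0.6)) + rnorm(n)
  pr <- linear_problem(X, y)
  spec <- criterion("bic")
  best <- all_subset_select(pr, spec)
  oracle <- brute_force_subsets(pr$X, pr$y, 1, log(n))
  expect_equal(which(best$support), oracle$support)
  expect_equal(best$criterion, oracle$criterion, tolerance = 1e-9)

  # orthonormal design: closed-form hard threshold n*bh^2/sigma2 > log(n)
  Xo <- make_orthonormal_design(n, 6, seed = 2)
  bh <- c(0.5, 0.05, -0.4, 0.28, -0.05, 0.6)
  pro <- linear_problem(Xo, drop(Xo %*% bh), standardize = FALSE)
  besto <- all_subset_select(pro, spec)
  expect_equal(which(besto$support), which(n * bh^2 > log(n)))

  expect_error(all_subset_select(linear_problem(matrix(rnorm(42 * 21), 42), rnorm(42)),
                                 spec), "p <= 20")
  # p = 1 reduces to a single comparison against the null
  pr1 <- linear_problem(X[, 1, drop = FALSE], y)
  b1 <- all_subset_select(pr1, spec)
  c0 <- evaluate_criterion(pr1, integer(0), spec)$criterion
  c1 <- evaluate_criterion(pr1, 1L, spec)$criterion
  expect_identical(any(b1$support), c1 < c0)
})

test_that("path selection minimizes over distinct supports with small-model ties", {
  set.seed(23)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:2] %*% c(1.5, -1.2)) + rnorm(n)
  pr <- linear_problem(X, y)
  path <- ar_lm_path(pr, lambdas = ar_lambda_grid(n, 1, 30))
  spec <- criterion("bic")
  best <- choose_on_path(path, spec)
  # the reported minimum is attained and no path support does better
  crits <- vapply(path$fits, function(f)
    evaluate_criterion(pr, f$support, spec)$criterion, numeric(1))
  expect_equal(best$criterion, min(crits), tolerance = 1e-12)
  # single-fit path returns that fit's support
  p1 <- ar_lm_path(pr, lambdas = 5)
  b1 <- choose_on_path(p1, spec)
  expect_equal(b1$support, p1$fits[[1]]$support)
})

test_that("global all-subset optimum dominates stepwise and path heuristics", {
  set.seed(29)
  spec <- criterion("bic")
  for (rep in 1:4) {
    n <- 60; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    k <- sample(0:4, 1)
    b <- numeric(p); if (k > 0) b[sample(p, k)] <- runif(k, 0.5, 1.5)
    y <- drop(X %*% b) + rnorm(n)
    pr <- linear_problem(X, y)
    c_all <- all_subset_select(pr, spec)$criterion
    c_sw <- stepwise_select(pr, spec)$criterion
    c_path <- choose_on_path(ar_lm_path(pr), spec)$criterion
    expect_lte(c_all, c_sw + 1e-9)
    expect_lte(c_all, c_path + 1e-9)
  }
})

test_that("stepwise selection recovers exact solutions in easy designs", {
  n <- 60
  Xo <- make_orthonormal_design(n, 8, seed = 3)
  y <- drop(Xo[, 1:2] %*% c(1, 1))  # noiseless two-effect model
  pr <- linear_problem(Xo, y, standardize = FALSE)
  spec <- criterion("bic")
  sw <- stepwise_select(pr, spec)
  expect_identical(which(sw$support), c(1L, 2L))
  # p <= top_m on an orthonormal design: identical to all-subset selection
  set.seed(71)
  bh <- rnorm(8, sd = 0.4)
  pr2 <- linear_problem(Xo, drop(Xo %*% bh) + rnorm(n), standardize = FALSE)
  expect_equal(stepwise_select(pr2, spec)$support,
               all_subset_select(pr2, spec)$support)
})

test_that("stepwise with mBIC stays near-null on pure noise", {
  set.seed(83)
  n <- 50; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  pr <- linear_problem(X, rnorm(n))
  spec <- criterion("mbic", c = 4, p_total = p)
  sw <- stepwise_select(pr, spec)
  exact <- all_subset_select(pr, spec)
  expect_lte(sw$size, 1)
  expect_lte(exact$criterion, sw$criterion + 1e-9)
})

test_that("marginal preselection ranks by single-regressor strength", {
  set.seed(37)
  n <- 100; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 3]  # noiseless copy
  pr <- linear_problem(X, y)
  sel <- marginal_preselect(pr, m = 1)
  expect_identical(sel$keep, 3L)
  # m = p keeps everything in order
  expect_identical(marginal_preselect(pr, m = p)$keep, 1:5)
  expect_warning(marginal_preselect(pr, m = p + 3), "exceeds p")
  expect_error(marginal_preselect(pr), "exactly one")
  expect_error(marginal_preselect(pr, m = 2, alpha = 0.1), "exactly one")
  # top-2 matches per-column OLS |t| ranking
  y2 <- drop(X %*% c(0.8, 0, 0.5, 0, 0.1)) + rnorm(n)
  pr2 <- linear_problem(X, y2)
  tstats <- vapply(1:p, function(j) {
    f <- summary(lm(pr2$y ~ pr2$X[, j] - 1))
    abs(f$coefficients[1, "t value"])
  }, numeric(1))
  sel2 <- marginal_preselect(pr2, m = 2)
  expect_setequal(sel2$keep, order(tstats, decreasing = TRUE)[1:2])
  # alpha-based thresholding returns a subset of columns
  sel3 <- marginal_preselect(pr2, alpha = 0.001)
  expect_true(all(sel3$keep %in% 1:p))
})
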