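# Shared fixtures and independent oracles, all built in code.

# n x p design with X^T X = n I (orthonormal up to the sqrt(n) scaling).
make_orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)
}

# Naive textbook weight formula, evaluated directly in double precision.
naive_weights <- function(beta, q = 0, delta = 1e-5, gamma = 2) {
  (abs(beta)^gamma + delta^gamma)^((q - 2) / gamma)
}

# Scalar AR map iterated to convergence: the independent oracle for the
# orthogonal-design limit.
scalar_ar_limit <- function(beta_hat, n, sigma2, lambda, delta = 1e-5,
                            max_iter = 200000) {
  b <- beta_hat
  for (k in seq_len(max_iter)) {
    b_old <- b
    w <- 1 / (b^2 + delta^2)
    b <- n * beta_hat / (n + lambda * sigma2 * w)
    if (abs(b - b_old) < 1e-13 * max(1, abs(b))) break
  }
  b
}

# Exhaustive segmentation search over all 2^(n-1) breakpoint patterns.
brute_force_segment <- function(y, lambda) {
  n <- length(y)
  best <- list(objective = Inf, breakpoints = integer(0))
  for (mask in 0:(2^(n - 1) - 1)) {
    bps <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    obj <- segment_objective(y, bps, lambda)
    if (obj < best$objective - 1e-12) best <- list(objective = obj, breakpoints = bps)
  }
  best
}

# Naive all-subset minimizer by per-subset lm refits (no precomputation).
brute_force_subsets <- function(X, y, sigma2, lambda_crit) {
  p <- ncol(X)
  best_crit <- sum(y^2) / sigma2
  best <- integer(0)
  for (mask in 1:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    rss <- sum(lm.fit(X[, idx, drop = FALSE], y)$residuals^2)
    crit <- rss / sigma2 + length(idx) * lambda_crit
    if (crit < best_crit - 1e-9) { best_crit <- crit; best <- idx }
  }
  list(support = best, criterion = best_crit)
}

# Dense tridiagonal solve of the smoothing normal equations:
# (I + lambda * D^T diag(w) D) mu = y with D the first-difference matrix.
dense_smooth <- function(y, lambda, w) {
  n <- length(y)
  D <- diff(diag(n))
  A <- diag(n) + lambda * t(D) %*% (w * D)
  drop(solve(A, y))
}
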