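#' Construct (and optionally standardize) a linear regression problem
#'
#' Bundles a design matrix and response with a known error variance. With
#' `standardize = TRUE` (the default) each column of `X` is centered and
#' scaled so its squared norm equals `n`, and `y` is centered; this is the
#' scaling under which the penalty calibration \eqn{\lambda = 4\tilde\lambda}
#' (see [l0_to_ar()]) applies. Centering/scaling factors are retained so
#' coefficients can be mapped back to the original scale.
#'
#' @param X Numeric design matrix (`n x p`).
#' @param y Numeric response of length `n`.
#' @param sigma2 Known error variance (default 1, as in the simulation
#'   settings this package reproduces).
#' @param standardize Center/scale as described above.
#' @return An object of class `"linear_problem"` with elements `X`, `y`, `n`,
#'   `p`, `sigma2`, `standardized`, `centers`, `scales`, `y_center`.
#' @export
#' @examples
#' pr <- linear_problem(matrix(rnorm(30), 10), rnorm(10))
#' colMeans(pr$X)            # ~0
#' colSums(pr$X^2)           # all equal to n
linear_problem <- function(X, y, sigma2 = 1, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!is.numeric(X) || any(!is.finite(X))) stop("`X` must be finite numeric")
  if (any(!is.finite(y))) stop("`y` must be finite numeric")
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 observations")
  if (length(y) != n) stop("`X` and `y` have incompatible dimensions")
  stopifnot(is.numeric(sigma2), sigma2 > 0)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  centers <- rep(0, p); scales <- rep(1, p); y_center <- 0
  if (standardize) {
    centers <- colMeans(X)
    Xc <- sweep(X, 2L, centers)
    ss <- sqrt(colSums(Xc^2) / n)
    bad <- which(ss < 1e-12)
    if (length(bad))
      stop("zero-variance column(s) after centering: ",
           paste(colnames(X)[bad], collapse = ", "))
    scales <- ss
    X <- sweep(Xc, 2L, scales, "/")
    y_center <- mean(y)
    y <- y - y_center
  }
  structure(
    list(X = X, y = y, n = n, p = p, sigma2 = sigma2,
         standardized = standardize, centers = centers, scales = scales,
         y_center = y_center),
    class = "linear_problem"
  )
}

#' @export
print.linear_problem <- function(x, ...) {
  cat(sprintf("Linear problem: n = %d, p = %d, sigma2 = %g%s\n",
              x$n, x$p, x$sigma2,
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Weighted ridge solve for a linear problem
#'
#' Solves \eqn{(X^T X + \tilde\lambda \sigma^2 \mathrm{diag}(w)) \beta = X^T y}
#' by a symmetric positive-definite (Cholesky) solve.
#'
#' @param problem A [linear_problem()].
#' @param lambda AR penalty \eqn{\tilde\lambda \ge 0}.
#' @param weights Non-negative weight vector of length `p`.
#' @return Coefficient vector of length `p`.
#' @export
weighted_ridge <- function(problem, lambda, weights) {
  stopifnot(inherits(problem, "linear_problem"), lambda >= 0)
  if (length(weights) != problem$p) stop("`weights` must have length p")
  if (any(weights < 0)) stop("`weights` must be non-negative")
  A <- crossprod(problem$X)
  diag(A) <- diag(A) + lambda * problem$sigma2 * weights
  b <- crossprod(problem$X, problem$y)
  sympd_solve(A, b)
}

# Cholesky solve with a clear error on (near-)singular systems.
sympd_solve <- function(A, b) {
  R <- tryCatch(chol(A), error = function(e)
    stop("singular system in weighted ridge solve (rank-deficient X with no penalty?)",
         call. = FALSE))
  drop(backsolve(R, forwardsolve(t(R), b)))
}

#' Map an L0 penalty to the equivalent adaptive ridge penalty
#'
#' Under orthogonal design, adaptive ridge at penalty \eqn{\tilde\lambda}
#' selects the same model as exact L0 minimization at \eqn{\lambda =
#' 4\tilde\lambda}; hence a selection criterion with per-parameter penalty
#' \eqn{\lambda} (2 for AIC, \eqn{\log n} for BIC, \eqn{\log(np^2/c^2)} for
#' mBIC) is targeted with \eqn{\tilde\lambda = \lambda/4}.
#'
#' @param lambda L0 per-parameter penalty \eqn{\lambda \ge 0}.
#' @return \eqn{\lambda/4}.
#' @export
#' @examples
#' l0_to_ar(log(50))  # BIC at n = 50
l0_to_ar <- function(lambda) {
  stopifnot(all(lambda >= 0))
  lambda / 4
}

#' Adaptive ridge fit of a linear model
#'
#' Iterates the closed-form weighted ridge solve and the adaptive weight
#' update until the selection indicators stabilize, then refits ordinary
#' least squares on the selected support.
#'
#' @param problem A [linear_problem()].
#' @param lambda AR penalty \eqn{\tilde\lambda \ge 0}. Note this is the
#'   *ridge-side* penalty; to target an L0 criterion penalty \eqn{\lambda}
#'   use [l0_to_ar()].
#' @param control An [ar_control()].
#' @param init_beta,init_weights Optional warm starts (used by [ar_lm_path()]).
#' @param keep_history Record the indicator trace per iteration.
#' @return An object of class `"ar_lm"`: `state` (final beta/weights/
#'   indicators), `support` (logical), `beta_refit` (OLS on the support,
#'   zero elsewhere, on the standardized scale), `rss`, `lambda`, `problem`.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 6), 50)
#' y <- X[, 1] - X[, 2] + rnorm(50)
#' fit <- ar_lm(linear_problem(X, y), lambda = l0_to_ar(log(50)))
#' which(fit$support)
ar_lm <- function(problem, lambda, control = ar_control(),
                  init_beta = NULL, init_weights = NULL,
                  keep_history = FALSE) {
  stopifnot(inherits(problem, "linear_problem"), lambda >= 0)
  p <- problem$p
  if (lambda > problem$n / problem$sigma2)
    warning("lambda exceeds n/sigma2; the L0 calibration lambda = 4*lambda_tilde no longer applies")
  w0 <- expand_init_weights(control, p)
  forced <- w0 == 0
  w <- if (is.null(init_weights)) w0 else {
    stopifnot(length(init_weights) == p)
    iw <- init_weights; iw[forced] <- 0; iw
  }
  A0 <- crossprod(problem$X)
  b <- crossprod(problem$X, problem$y)
  ridge_eps <- 0
  if (lambda == 0 && qr(problem$X)$rank < p) {
    warning("rank-deficient design with lambda = 0; adding ridge 1e-10 for solvability")
    ridge_eps <- 1e-10
  }
  ind <- rep(Inf, p)
  history <- if (keep_history) list() else NULL
  converged <- FALSE
  iter <- 0L
  beta <- init_beta
  beta_prev <- NULL
  repeat {
    iter <- iter + 1L
    A <- A0
    diag(A) <- diag(A) + lambda * problem$sigma2 * w + ridge_eps
    beta <- sympd_solve(A, b)
    w <- ar_update_weights(beta, control, forced = forced)
    ind_new <- ar_indicators(beta, w)
    if (keep_history) history[[iter]] <- ind_new
    if (!is.null(beta_prev) &&
        ar_converged(ind, ind_new, control$tol,
                     beta_prev, beta, control$beta_tol)) {
      converged <- TRUE; ind <- ind_new; break
    }
    ind <- ind_new
    beta_prev <- beta
    if (iter >= control$max_iter) break
  }
  if (!converged)
    warning(sprintf("adaptive ridge did not converge in %d iterations", control$max_iter))
  state <- ar_state(beta, w, iter, converged)
  support <- ar_support(beta, w, forced = forced)
  refit <- ols_refit(problem, support)
  structure(
    list(state = state, support = support, beta_refit = refit$beta,
         rss = refit$rss, lambda = lambda, forced = forced,
         history = if (keep_history) do.call(rbind, history) else NULL,
         problem = problem),
    class = "ar_lm"
  )
}

# OLS refit on a logical support; returns full-length beta (zeros off-support).
ols_refit <- function(problem, support) {
  beta <- numeric(problem$p)
  if (!any(support)) return(list(beta = beta, rss = sum(problem$y^2)))
  fit <- lm.fit(problem$X[, support, drop = FALSE], problem$y)
  beta[support] <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta, rss = sum(fit$residuals^2))
}

#' @export
print.ar_lm <- function(x, ...) {
  cat(sprintf(
    "Adaptive ridge linear fit: lambda = %.4g, %d/%d selected, RSS = %.4g (%s in %d iterations)\n",
    x$lambda, sum(x$support), length(x$support), x$rss,
    if (x$state$converged) "converged" else "NOT converged", x$state$iteration))
  invisible(x)
}

#' Default increasing penalty grid for adaptive ridge paths
#'
#' 100 log-spaced values from \eqn{10^{-4} n/\sigma^2} to \eqn{n/\sigma^2}.
#' AR paths traverse *increasing* penalties (the reverse of the lasso
#' convention): the warm start carries forward which coordinates have already
#' been driven to zero.
#'
#' @param n Sample size.
#' @param sigma2 Error variance.
#' @param length.out Grid size.
#' @return Strictly increasing numeric vector.
#' @export
ar_lambda_grid <- function(n, sigma2 = 1, length.out = 100L) {
  top <- n / sigma2
  exp(seq(log(1e-4 * top), log(top), length.out = length.out))
}

#' Warm-started adaptive ridge regularization path (linear model)
#'
#' Fits [ar_lm()] over an increasing penalty grid, initializing each fit's
#' coefficients and weights from the previous fit's finals.
#'
#' @inheritParams ar_lm
#' @param lambdas Strictly increasing penalty grid; defaults to
#'   [ar_lambda_grid()].
#' @return An object of class `"ar_path"`: `lambdas`, `fits` (list of
#'   `"ar_lm"`), `support_sizes`.
#' @export
ar_lm_path <- function(problem, lambdas = NULL, control = ar_control()) {
  stopifnot(inherits(problem, "linear_problem"))
  if (is.null(lambdas)) lambdas <- ar_lambda_grid(problem$n, problem$sigma2)
  check_lambda_grid(lambdas)
  fits <- vector("list", length(lambdas))
  init_beta <- NULL; init_weights <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- suppressWarnings(
      ar_lm(problem, lambdas[i], control,
            init_beta = init_beta, init_weights = init_weights))
    init_beta <- fits[[i]]$state$beta
    init_weights <- fits[[i]]$state$weights
  }
  structure(
    list(lambdas = lambdas, fits = fits,
         support_sizes = vapply(fits, function(f) sum(f$support), integer(1)),
         family = "gaussian", problem = problem),
    class = "ar_path"
  )
}

check_lambda_grid <- function(lambdas) {
  if (length(lambdas) < 1L || any(diff(lambdas) <= 0) || any(lambdas < 0))
    stop("`lambdas` must be a non-negative strictly increasing grid")
}

#' @export
print.ar_path <- function(x, ...) {
  cat(sprintf(
    "Adaptive ridge path (%s): %d penalties in [%.3g, %.3g], support sizes %d..%d\n",
    x$family, length(x$lambdas), min(x$lambdas), max(x$lambdas),
    min(x$support_sizes), max(x$support_sizes)))
  invisible(x)
}

#' Plug-in estimate of the error variance
#'
#' Optional helper for when \eqn{\sigma^2} is unknown: with `p < n` the
#' full-model residual variance \eqn{\mathrm{RSS}/(n-p)}; otherwise the
#' residual variance of the refit on a supplied support. It is never applied
#' automatically — [linear_problem()] defaults to a known `sigma2 = 1` —
#' because the orthogonal-design theory and the reproduced simulations
#' assume a known variance.
#'
#' @param problem A [linear_problem()].
#' @param support Optional logical mask or index set to refit on when
#'   `p >= n` (required in that case).
#' @return A positive scalar.
#' @export
estimate_sigma2 <- function(problem, support = NULL) {
  stopifnot(inherits(problem, "linear_problem"))
  n <- problem$n; p <- problem$p
  if (p < n - 1L && is.null(support)) {
    rss <- sum(lm.fit(problem$X, problem$y)$residuals^2)
    return(rss / (n - p))
  }
  if (is.null(support))
    stop("p >= n: supply a `support` to base the variance estimate on")
  if (!is.logical(support)) support <- seq_len(p) %in% support
  k <- sum(support)
  if (k >= n) stop("support too large for a variance estimate")
  rss <- ols_refit(problem, support)$rss
  rss / (n - k)
}

#' Adaptive ridge fit with random weight restarts
#'
#' The AR map is not a contraction and its limit can depend on the initial
#' weights. This wrapper runs [ar_lm()] from the all-ones start plus
#' `restarts` random starts with weights drawn uniformly on `[0.5, 1.5]`
#' (seeded), evaluates the criterion at each limit's ML refit, and returns
#' the best fit.
#'
#' @inheritParams ar_lm
#' @param spec A [criterion()] used to rank the limits.
#' @param restarts Number of random restarts.
#' @param seed Seed for the restart draws.
#' @return The best `"ar_lm"` fit, with `criterion` and `n_restarts` added.
#' @export
ar_lm_restarts <- function(problem, lambda, spec = criterion(),
                           control = ar_control(), restarts = 5, seed = 1) {
  fits <- vector("list", restarts + 1L)
  fits[[1]] <- suppressWarnings(ar_lm(problem, lambda, control))
  set.seed(seed)
  w0 <- expand_init_weights(control, problem$p)
  for (r in seq_len(restarts)) {
    w <- stats::runif(problem$p, 0.5, 1.5)
    w[w0 == 0] <- 0
    fits[[r + 1L]] <- suppressWarnings(
      ar_lm(problem, lambda, control, init_weights = w))
  }
  crit <- vapply(fits, function(f)
    evaluate_criterion(problem, f$support, spec)$criterion, numeric(1))
  best <- fits[[which.min(crit)]]
  best$criterion <- min(crit)
  best$n_restarts <- restarts
  best
}

#' Orthogonal-design fixed point of the scalar adaptive ridge map
#'
#' In the orthonormal case (\eqn{X^T X = n I}) each coordinate evolves
#' independently under \eqn{\beta \gets n\hat\beta / (n + \tilde\lambda
#' \sigma^2/(\beta^2+\delta^2))}. In the \eqn{\delta \to 0} limit the stable
#' fixed point is 0 when \eqn{\hat\beta^2 < 4\tilde\lambda\sigma^2/n} and
#' \eqn{(\hat\beta + \sqrt{\hat\beta^2 - 4\tilde\lambda\sigma^2/n})/2}
#' otherwise (the discriminant-zero boundary returns \eqn{\hat\beta/2}).
#'
#' @param beta_hat OLS estimate of the coordinate.
#' @param n Sample size.
#' @param sigma2 Error variance.
#' @param lambda AR penalty \eqn{\tilde\lambda}.
#' @return The limiting AR coefficient.
#' @export
orthogonal_fixed_point <- function(beta_hat, n, sigma2, lambda) {
  thr <- 4 * lambda * sigma2 / n
  out <- numeric(length(beta_hat))
  keep <- beta_hat^2 >= thr
  disc <- pmax(beta_hat[keep]^2 - thr, 0)
  out[keep] <- (beta_hat[keep] + sign(beta_hat[keep]) * sqrt(disc)) / 2
  out
}
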