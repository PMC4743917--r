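#' Construct a Poisson regression problem
#'
#' Counts are modelled as \eqn{y_i \sim \mathrm{Poisson}(\mu_i)} with
#' \eqn{\mu_i = \exp(X_i \beta + o_i)} and log link. No intercept is added:
#' include a column of ones (and force it in via a zero initial weight in
#' [ar_control()]) if an unpenalized intercept is wanted.
#'
#' @param X Numeric design matrix.
#' @param y Non-negative integer counts.
#' @param offset Optional log-offset vector (default 0).
#' @return An object of class `"poisson_problem"`.
#' @export
poisson_problem <- function(X, y, offset = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (any(!is.finite(X))) stop("`X` must be finite numeric")
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y)))
    stop("`y` must be non-negative integer counts")
  n <- nrow(X)
  if (length(y) != n) stop("`X` and `y` have incompatible dimensions")
  if (is.null(offset)) offset <- rep(0, n)
  stopifnot(length(offset) == n, all(is.finite(offset)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, y = y, n = n, p = ncol(X), offset = offset),
            class = "poisson_problem")
}

#' @export
print.poisson_problem <- function(x, ...) {
  cat(sprintf("Poisson problem: n = %d, p = %d, mean count %.3g\n",
              x$n, x$p, mean(x$y)))
  invisible(x)
}

#' Poisson log-likelihood (additive constant dropped)
#'
#' Returns \eqn{\beta^T X^T y - \mathbf{1}^T \exp(X\beta)} (offset included in
#' the linear predictor). The \eqn{\sum \log y_i!} term is omitted; it cancels
#' in every model comparison this package makes.
#'
#' @param problem A [poisson_problem()].
#' @param beta Coefficient vector.
#' @return A scalar.
#' @export
poisson_loglik <- function(problem, beta) {
  stopifnot(inherits(problem, "poisson_problem"), all(is.finite(beta)))
  eta <- drop(problem$X %*% beta) + problem$offset
  if (max(eta) > 700)
    stop("exp overflow in the Poisson likelihood; consider rescaling the design")
  sum(problem$y * eta) - sum(exp(eta))
}

#' Weighted-ridge Poisson solve (Newton-Raphson)
#'
#' Maximizes the penalized log-likelihood \eqn{\ell(\beta) = \beta^T X^T y -
#' \mathbf{1}^T \exp(X\beta) - (\lambda/2)\beta^T \mathrm{diag}(w)\beta} by
#' Newton steps \eqn{\beta \gets \beta - H^{-1}\nabla} with step-halving so
#' each accepted step does not decrease the objective. Stops when
#' \eqn{\|\nabla\|_\infty < 10^{-8}} or after 100 steps.
#'
#' @param problem A [poisson_problem()].
#' @param lambda Ridge penalty \eqn{\lambda \ge 0}.
#' @param weights Non-negative weights of length `p`.
#' @param init Starting coefficients (default 0).
#' @param grad_tol,max_newton Stopping controls.
#' @return Coefficient vector with attributes `iterations` and `converged`.
#' @export
poisson_ridge <- function(problem, lambda, weights, init = NULL,
                          grad_tol = 1e-8, max_newton = 100L) {
  stopifnot(inherits(problem, "poisson_problem"), lambda >= 0)
  p <- problem$p
  if (length(weights) != p || any(weights < 0))
    stop("`weights` must be non-negative of length p")
  if (is.null(init)) init <- numeric(p)
  stopifnot(length(init) == p)
  res <- if (all(problem$offset == 0)) {
    cpp_poisson_ridge(problem$X, problem$y, lambda, weights, init,
                      grad_tol, as.integer(max_newton))
  } else {
    poisson_ridge_offset(problem, lambda, weights, init, grad_tol, max_newton)
  }
  if (!res$converged)
    stop(structure(class = c("poisson_ridge_error", "error", "condition"),
                   list(message = sprintf(
                     "Poisson Newton solver did not reach gradient tolerance in %d steps",
                     max_newton),
                        call = sys.call(-1), beta = res$beta)))
  beta <- drop(res$beta)
  attr(beta, "iterations") <- res$iterations
  attr(beta, "converged") <- res$converged
  beta
}

# Offset-aware fallback in plain R (offsets are rare in the simulations).
poisson_ridge_offset <- function(problem, lambda, weights, init,
                                 grad_tol, max_newton) {
  beta <- init
  X <- problem$X; y <- problem$y; off <- problem$offset
  penlik <- function(b) {
    eta <- drop(X %*% b) + off
    if (max(eta) > 700) return(-Inf)
    sum(y * eta) - sum(exp(eta)) - lambda / 2 * sum(weights * b^2)
  }
  ll <- penlik(beta)
  converged <- FALSE; it <- 0L
  while (it < max_newton) {
    it <- it + 1L
    mu <- exp(drop(X %*% beta) + off)
    grad <- drop(crossprod(X, y - mu)) - lambda * weights * beta
    if (max(abs(grad)) < grad_tol) { converged <- TRUE; it <- it - 1L; break }
    H <- crossprod(X, X * mu)
    diag(H) <- diag(H) + lambda * weights
    step <- solve(H, grad)
    t <- 1; accepted <- FALSE
    for (h in 1:50) {
      cand <- beta + t * step
      llc <- penlik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) {
        beta <- cand; ll <- llc; accepted <- TRUE; break
      }
      t <- t / 2
    }
    if (!accepted) break
  }
  list(beta = beta, iterations = it, converged = converged)
}

#' Adaptive ridge fit of a Poisson regression
#'
#' Alternates the weighted-ridge Newton solve (warm-started at the previous
#' outer iterate) with the adaptive weight update until the selection
#' indicators stabilize, then refits unpenalized Poisson maximum likelihood
#' on the selected support.
#'
#' @inheritParams ar_lm
#' @param problem A [poisson_problem()].
#' @return An object of class `"ar_poisson"`: `state`, `support`,
#'   `beta_refit`, `loglik_refit`, `lambda`, `newton_iters_total`.
#' @export
ar_poisson <- function(problem, lambda, control = ar_control(),
                       init_beta = NULL, init_weights = NULL) {
  stopifnot(inherits(problem, "poisson_problem"), lambda >= 0)
  p <- problem$p
  w0 <- expand_init_weights(control, p)
  forced <- w0 == 0
  w <- if (is.null(init_weights)) w0 else {
    stopifnot(length(init_weights) == p)
    iw <- init_weights; iw[forced] <- 0; iw
  }
  beta <- if (is.null(init_beta)) numeric(p) else init_beta
  ind <- rep(Inf, p)
  converged <- FALSE; iter <- 0L; newton_total <- 0L
  beta_prev <- NULL
  repeat {
    iter <- iter + 1L
    beta <- poisson_ridge(problem, lambda, w, init = beta)
    newton_total <- newton_total + attr(beta, "iterations")
    beta <- as.numeric(beta)
    w <- ar_update_weights(beta, control, forced = forced)
    ind_new <- ar_indicators(beta, w)
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
    warning(sprintf("adaptive ridge (Poisson) did not converge in %d iterations",
                    control$max_iter))
  state <- ar_state(beta, w, iter, converged)
  support <- ar_support(beta, w, forced = forced)
  refit <- poisson_refit(problem, support)
  structure(
    list(state = state, support = support, beta_refit = refit$beta,
         loglik_refit = refit$loglik, lambda = lambda, forced = forced,
         newton_iters_total = newton_total, problem = problem),
    class = "ar_poisson"
  )
}

# Unpenalized Poisson ML refit on a logical support (glm.fit; no intercept).
poisson_refit <- function(problem, support) {
  beta <- numeric(problem$p)
  if (!any(support))
    return(list(beta = beta, loglik = poisson_loglik(problem, beta)))
  fit <- suppressWarnings(
    stats::glm.fit(problem$X[, support, drop = FALSE], problem$y,
                   family = stats::poisson(), offset = problem$offset,
                   intercept = FALSE))
  beta[support] <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta, loglik = poisson_loglik(problem, beta))
}

#' @export
print.ar_poisson <- function(x, ...) {
  cat(sprintf(
    "Adaptive ridge Poisson fit: lambda = %.4g, %d/%d selected, refit loglik = %.4g (%s)\n",
    x$lambda, sum(x$support), length(x$support), x$loglik_refit,
    if (x$state$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Warm-started adaptive ridge path for Poisson regression
#'
#' @inheritParams ar_lm_path
#' @param problem A [poisson_problem()].
#' @return An `"ar_path"` object with `family = "poisson"`.
#' @export
ar_poisson_path <- function(problem, lambdas = NULL, control = ar_control()) {
  stopifnot(inherits(problem, "poisson_problem"))
  if (is.null(lambdas)) lambdas <- ar_lambda_grid(problem$n)
  check_lambda_grid(lambdas)
  fits <- vector("list", length(lambdas))
  init_beta <- NULL; init_weights <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- suppressWarnings(
      ar_poisson(problem, lambdas[i], control,
                 init_beta = init_beta, init_weights = init_weights))
    init_beta <- fits[[i]]$state$beta
    init_weights <- fits[[i]]$state$weights
  }
  structure(
    list(lambdas = lambdas, fits = fits,
         support_sizes = vapply(fits, function(f) sum(f$support), integer(1)),
         family = "poisson", problem = problem),
    class = "ar_path"
  )
}
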