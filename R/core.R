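#' Control parameters for the adaptive ridge iteration
#'
#' The adaptive ridge (AR) procedure alternates a weighted ridge solve with a
#' component-wise weight update \eqn{w_j = (|\beta_j|^\gamma +
#' \delta^\gamma)^{(q-2)/\gamma}}. For the variable-selection case `q = 0`
#' with `gamma = 2` the effective per-coordinate penalty
#' \eqn{w_j \beta_j^2 = \beta_j^2 / (\beta_j^2 + \delta^2)} converges to 0 or 1,
#' so the quadratic penalty mimics an L0 (best-subset) penalty.
#'
#' @param q Penalty exponent in `[0, 2)`. Only `q = 0` (L0 selection) is
#'   exercised by the solvers' downstream selection logic; other values are
#'   exposed for experimentation.
#' @param delta Smoothing constant \eqn{\delta > 0}; effect sizes below
#'   `delta` are driven to zero. Default `1e-5`.
#' @param gamma Sharpness \eqn{\gamma > 0} of the thresholding approximation.
#'   Default 2.
#' @param tol Convergence tolerance on the selection indicators
#'   \eqn{w_j \beta_j^2} (max absolute change between iterations).
#' @param beta_tol Additional relative tolerance on the coefficient change:
#'   convergence also requires \eqn{\max_j |\Delta\beta_j| <
#'   \mathrm{beta\_tol} \cdot \max(1, \|\beta\|_\infty)}. Needed because a
#'   coefficient sliding slowly toward zero keeps its indicator pinned near 1
#'   until it passes the `delta` scale, so the indicator test alone can stop
#'   prematurely.
#' @param max_iter Iteration cap for the outer AR loop.
#' @param init_weights Non-negative initial weights: a scalar (recycled) or a
#'   vector. An entry of exactly 0 marks a forced-in (never penalized, always
#'   selected) coordinate and stays 0 at every iteration.
#'
#' @return An object of class `"ar_control"`.
#' @export
#' @examples
#' ar_control()
#' ar_control(init_weights = c(0, 1, 1))  # first coefficient forced in
ar_control <- function(q = 0, delta = 1e-5, gamma = 2, tol = 1e-8,
                       beta_tol = 1e-9, max_iter = 1000L, init_weights = 1) {
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0, q < 2)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive number")
  stopifnot(is.numeric(tol), tol > 0, is.numeric(beta_tol), beta_tol > 0)
  max_iter <- as.integer(max_iter)
  stopifnot(max_iter >= 1L)
  if (any(!is.finite(init_weights)) || any(init_weights < 0))
    stop("`init_weights` must be non-negative and finite")
  structure(
    list(q = q, delta = delta, gamma = gamma, tol = tol, beta_tol = beta_tol,
         max_iter = max_iter, init_weights = init_weights),
    class = "ar_control"
  )
}

#' @export
print.ar_control <- function(x, ...) {
  cat(sprintf(
    "Adaptive ridge control: q = %g, delta = %g, gamma = %g, tol = %g, max_iter = %d\n",
    x$q, x$delta, x$gamma, x$tol, x$max_iter))
  invisible(x)
}

# Expand scalar/vector init_weights to length p; validates length.
expand_init_weights <- function(control, p) {
  w <- control$init_weights
  if (length(w) == 1L) w <- rep(w, p)
  if (length(w) != p)
    stop(sprintf("`init_weights` has length %d but the problem has %d coefficients",
                 length(w), p))
  w
}

#' Adaptive ridge weight update
#'
#' Computes \eqn{w_j = (|\beta_j|^\gamma + \delta^\gamma)^{(q-2)/\gamma}}
#' through a numerically stable two-branch `log1p` form that never adds
#' \eqn{|\beta_j|^\gamma} and \eqn{\delta^\gamma} directly (those can differ by
#' hundreds of orders of magnitude). For `q = 0`, `gamma = 2` this is
#' \eqn{1 / (\beta_j^2 + \delta^2)}.
#'
#' Coordinates whose entry in `forced` is `TRUE` (equivalently whose initial
#' weight was 0) are never penalized: their weight is held at exactly 0.
#'
#' @param beta Numeric coefficient vector (finite).
#' @param control An [ar_control()] object.
#' @param forced Optional logical vector marking forced-in coordinates.
#' @return Numeric weight vector of the same length as `beta`.
#' @export
#' @examples
#' ar_update_weights(c(0, 1e-3, 1), ar_control())
ar_update_weights <- function(beta, control = ar_control(), forced = NULL) {
  if (any(!is.finite(beta))) stop("`beta` contains non-finite values")
  q <- control$q; delta <- control$delta; gamma <- control$gamma
  ab <- abs(beta)
  e <- (q - 2) / gamma
  small <- ab <= delta
  w <- numeric(length(beta))
  # |beta| <= delta: w = delta^(q-2) * exp(e * log1p((|beta|/delta)^gamma))
  if (any(small))
    w[small] <- delta^(q - 2) * exp(e * log1p((ab[small] / delta)^gamma))
  # |beta| > delta: w = |beta|^(q-2) * exp(e * log1p((delta/|beta|)^gamma))
  if (any(!small))
    w[!small] <- ab[!small]^(q - 2) * exp(e * log1p((delta / ab[!small])^gamma))
  if (!is.null(forced)) w[forced] <- 0
  w
}

#' Selection indicators of an adaptive ridge state
#'
#' The per-coordinate quantity \eqn{w_j \beta_j^2}; for `q = 0` this equals
#' \eqn{\beta_j^2/(\beta_j^2+\delta^2)}, lies in `[0, 1)` and converges to 1
#' for retained and 0 for dropped coordinates. Convergence of the AR loop is
#' declared on these indicators.
#'
#' @param beta Coefficient vector.
#' @param weights Weight vector of the same length.
#' @return Numeric vector of indicators.
#' @export
ar_indicators <- function(beta, weights) {
  if (length(beta) != length(weights))
    stop("`beta` and `weights` must have the same length")
  weights * beta^2
}

#' Quadratic penalty value of a weighted ridge state
#'
#' Returns \eqn{(\lambda/2) \sum_j w_j \beta_j^2}.
#'
#' @param beta,weights Coefficients and weights (same length).
#' @param lambda Penalty \eqn{\lambda \ge 0}.
#' @return A scalar.
#' @export
ar_penalty_value <- function(beta, weights, lambda) {
  stopifnot(lambda >= 0)
  if (length(beta) != length(weights))
    stop("`beta` and `weights` must have the same length")
  (lambda / 2) * sum(weights * beta^2)
}

#' Selected support of an adaptive ridge state
#'
#' Coordinate `j` is selected iff its indicator \eqn{w_j \beta_j^2}
#' strictly exceeds 0.5 (the midpoint of the limiting values 0 and 1), or it
#' is forced in. With `q = 0` the boundary case \eqn{|\beta_j| = \delta}
#' gives indicator exactly 0.5 and is not selected.
#'
#' @inheritParams ar_indicators
#' @param forced Optional logical vector of forced-in coordinates.
#' @return Logical selection mask.
#' @export
ar_support <- function(beta, weights, forced = NULL) {
  sel <- ar_indicators(beta, weights) > 0.5
  if (!is.null(forced)) sel <- sel | forced
  sel
}

# Convergence test used by every AR outer loop: the selection indicators must
# have stabilized AND (when the previous iterate is supplied) the coefficients
# themselves, in relative terms. A coordinate drifting slowly to zero keeps an
# indicator of ~1 until it crosses the delta scale, so the indicator test
# alone is not sufficient.
ar_converged <- function(ind_prev, ind_curr, tol,
                         beta_prev = NULL, beta_curr = NULL, beta_tol = 0) {
  ok <- max(abs(ind_curr - ind_prev)) < tol
  if (ok && !is.null(beta_prev))
    ok <- max(abs(beta_curr - beta_prev)) <
      beta_tol * max(1, max(abs(beta_curr)))
  ok
}

# Assemble the iteration state bundled with every fit.
ar_state <- function(beta, weights, iteration, converged) {
  list(beta = beta, weights = weights,
       indicators = ar_indicators(beta, weights),
       iteration = iteration, converged = converged)
}
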