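#' Weighted smoothing of an ordered signal (exact O(n) solve)
#'
#' Minimizes \eqn{\sum_i (y_i-\mu_i)^2 + \lambda \sum_i w_i
#' (\mu_{i+1}-\mu_i)^2} exactly, via a forward recursion expressing
#' \eqn{\mu_i = a_i + b_i \mu_{i+1}} followed by back-substitution — a
#' specialized symmetric tridiagonal solve that runs in O(n).
#'
#' @param y Ordered numeric signal of length `n >= 2`.
#' @param lambda Penalty \eqn{\lambda \ge 0}.
#' @param weights Non-negative difference weights of length `n - 1`.
#' @return Fitted mean vector \eqn{\mu} of length `n`.
#' @export
#' @examples
#' weighted_smooth(c(0, 2), lambda = 1, weights = 1)  # c(2/3, 4/3)
weighted_smooth <- function(y, lambda, weights) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("signal must have length >= 2")
  if (any(!is.finite(y))) stop("`y` must be finite")
  stopifnot(lambda >= 0)
  if (length(weights) == 1L) weights <- rep(weights, n - 1L)
  if (length(weights) != n - 1L) stop("`weights` must have length n - 1")
  if (any(weights < 0)) stop("`weights` must be non-negative")
  cpp_weighted_smooth(y, lambda, weights)
}

#' Adaptive ridge segmentation of an ordered signal
#'
#' Approximates the L0 changepoint fit \eqn{\min_\mu \sum (y_i-\mu_i)^2 +
#' \lambda \sum 1(\mu_i \ne \mu_{i+1})} by iterating [weighted_smooth()] with
#' the adaptive difference-weight update \eqn{w_i = (\delta^2 +
#' (\mu_{i+1}-\mu_i)^2)^{-1}} from \eqn{w^{(0)} = 1}. A breakpoint is declared
#' after position `i` when the difference indicator
#' \eqn{w_i(\mu_{i+1}-\mu_i)^2} exceeds 0.5; segment means are then refit as
#' arithmetic means (the exact per-segment minimizer), since the smoothed
#' \eqn{\mu} retains residual shrinkage.
#'
#' The penalty calibration differs from regression: targeting the L0 penalty
#' \eqn{\lambda = 2\log n} works well with the rescaled AR penalty
#' \eqn{\tilde\lambda = \lambda/\mathrm{scale}} with `scale = 6` (see the
#' package vignette; [calibrate_segment_scale()] recomputes this).
#'
#' @param y Ordered numeric signal.
#' @param lambda AR penalty \eqn{\tilde\lambda \ge 0} applied to squared
#'   differences.
#' @param control An [ar_control()].
#' @return An object of class `"ar_segmentation"`: `mu` (final smoothed
#'   means), `breakpoints` (1-based indices `i`, change between `i` and
#'   `i+1`), `segment_means` (refit), `fitted` (refit means per position),
#'   `diff_weights`, `lambda`, `state` (iteration/convergence info).
#' @export
#' @examples
#' y <- c(rep(0, 5), rep(5, 5))
#' ar_segment(y, lambda = 1)$breakpoints  # 5
ar_segment <- function(y, lambda, control = ar_control()) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("signal must have length >= 2")
  stopifnot(lambda >= 0)
  w <- rep(1, n - 1L)
  ind <- rep(Inf, n - 1L)
  converged <- FALSE; iter <- 0L
  mu <- y
  mu_prev <- NULL
  repeat {
    iter <- iter + 1L
    mu <- cpp_weighted_smooth(y, lambda, w)
    d <- diff(mu)
    w <- ar_update_weights(d, control)
    ind_new <- w * d^2
    if (!is.null(mu_prev) &&
        ar_converged(ind, ind_new, control$tol,
                     mu_prev, mu, control$beta_tol)) {
      converged <- TRUE; ind <- ind_new; break
    }
    ind <- ind_new
    mu_prev <- mu
    if (iter >= control$max_iter) break
  }
  if (!converged)
    warning(sprintf("adaptive ridge segmentation did not converge in %d iterations",
                    control$max_iter))
  breakpoints <- which(ind > 0.5)
  seg <- segment_refit(y, breakpoints)
  structure(
    list(mu = mu, breakpoints = breakpoints, segment_means = seg$means,
         fitted = seg$fitted, diff_weights = w, lambda = lambda,
         state = list(iteration = iter, converged = converged, indicators = ind),
         y = y),
    class = "ar_segmentation"
  )
}

# Piecewise-constant refit given breakpoints (1-based, change after index i).
segment_refit <- function(y, breakpoints) {
  n <- length(y)
  starts <- c(1L, breakpoints + 1L)
  ends <- c(breakpoints, n)
  means <- vapply(seq_along(starts),
                  function(k) mean(y[starts[k]:ends[k]]), numeric(1))
  fitted <- rep(means, times = ends - starts + 1L)
  list(means = means, fitted = fitted, starts = starts, ends = ends)
}

#' Penalized segmentation objective
#'
#' Evaluates \eqn{\mathrm{RSS} + \lambda \cdot \#\mathrm{breakpoints}} for a
#' given breakpoint set with segment means refit as arithmetic means.
#'
#' @param y Signal.
#' @param breakpoints 1-based breakpoint indices (possibly empty).
#' @param lambda L0 penalty per breakpoint.
#' @return A scalar.
#' @export
segment_objective <- function(y, breakpoints, lambda) {
  seg <- segment_refit(y, breakpoints)
  sum((y - seg$fitted)^2) + lambda * length(breakpoints)
}

#' Exact L0 segmentation by dynamic programming
#'
#' Minimizes \eqn{\sum (y_i-\mu_i)^2 + \lambda \cdot \#\mathrm{breakpoints}}
#' exactly over all segmentations with at most `kmax` segments, using the
#' classical k-segment dynamic program on prefix-sum costs
#' (O(`kmax` n^2)). Among equal-cost solutions it prefers fewer segments,
#' then leftmost breakpoints.
#'
#' @param y Ordered numeric signal.
#' @param lambda Penalty per breakpoint.
#' @param kmax Maximum number of segments (default `min(n, 25)`).
#' @return An `"ar_segmentation"`-like object of class `"dp_segmentation"`
#'   with `breakpoints`, `segment_means`, `fitted`, `objective`, `rss`.
#' @export
dp_segment <- function(y, lambda, kmax = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("empty signal")
  stopifnot(lambda >= 0)
  if (is.null(kmax)) kmax <- min(n, 25L)
  kmax <- as.integer(kmax)
  if (kmax < 1L || kmax > n) stop("`kmax` must be in 1..n")
  res <- cpp_dp_segment(y, lambda, kmax)
  bps <- as.integer(res$breakpoints)
  seg <- segment_refit(y, bps)
  structure(
    list(breakpoints = bps, segment_means = seg$means, fitted = seg$fitted,
         rss = res$rss, objective = res$objective, k = res$k,
         lambda = lambda, y = y),
    class = "dp_segmentation"
  )
}

#' @export
print.ar_segmentation <- function(x, ...) {
  cat(sprintf(
    "Adaptive ridge segmentation: n = %d, lambda = %.4g, %d breakpoint(s) at {%s}\n",
    length(x$y), x$lambda, length(x$breakpoints),
    paste(x$breakpoints, collapse = ", ")))
  invisible(x)
}

#' @export
print.dp_segmentation <- function(x, ...) {
  cat(sprintf(
    "Exact DP segmentation: n = %d, lambda = %.4g, %d breakpoint(s), objective %.4g\n",
    length(x$y), x$lambda, length(x$breakpoints), x$objective))
  invisible(x)
}

#' Calibrate the segmentation penalty rescaling factor
#'
#' For the L0 penalty \eqn{\lambda} (typically \eqn{2\log n}), runs AR
#' segmentation at \eqn{\lambda/s} for each candidate integer divisor `s` on
#' replicated noisy step signals, scores each run by its excess penalized
#' objective over the exact DP optimum at \eqn{\lambda}, and returns the
#' divisor minimizing the mean excess.
#'
#' @param signals A list of numeric signals (replicates).
#' @param lambda The L0 penalty the calibration targets.
#' @param scales Candidate integer divisors.
#' @param control An [ar_control()].
#' @return A list: `best_scale`, and `excess` (a [tibble::tibble] with one
#'   row per candidate scale: mean excess objective and the fraction of
#'   replicates within `2` of the DP optimum).
#' @export
calibrate_segment_scale <- function(signals, lambda, scales = 2:10,
                                    control = ar_control()) {
  stopifnot(is.list(signals), length(signals) >= 1L)
  dp_obj <- vapply(signals, function(y) dp_segment(y, lambda)$objective,
                   numeric(1))
  rows <- lapply(scales, function(s) {
    exc <- vapply(seq_along(signals), function(i) {
      fit <- suppressWarnings(ar_segment(signals[[i]], lambda / s, control))
      segment_objective(signals[[i]], fit$breakpoints, lambda) - dp_obj[i]
    }, numeric(1))
    tibble::tibble(scale = s, mean_excess = mean(exc),
                   frac_close = mean(exc <= 2))
  })
  excess <- do.call(rbind, rows)
  list(best_scale = excess$scale[which.min(excess$mean_excess)],
       excess = excess)
}
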