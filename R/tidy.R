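# broom-style tidiers for fitted objects.

#' @export
tidy.ar_lm <- function(x, ...) {
  tibble::tibble(
    term = colnames(x$problem$X),
    estimate = x$beta_refit,
    shrunken = x$state$beta,
    indicator = x$state$indicators,
    selected = x$support
  )
}

#' @export
glance.ar_lm <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, n_selected = sum(x$support), rss = x$rss,
    iterations = x$state$iteration, converged = x$state$converged
  )
}

#' @export
tidy.ar_poisson <- function(x, ...) {
  tibble::tibble(
    term = colnames(x$problem$X),
    estimate = x$beta_refit,
    shrunken = x$state$beta,
    indicator = x$state$indicators,
    selected = x$support
  )
}

#' @export
glance.ar_poisson <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, n_selected = sum(x$support),
    loglik = x$loglik_refit, iterations = x$state$iteration,
    converged = x$state$converged,
    newton_iterations = x$newton_iters_total
  )
}

#' @export
tidy.ar_path <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$lambdas), function(i) {
    f <- x$fits[[i]]
    tibble::tibble(lambda = x$lambdas[i],
                   term = colnames(x$problem$X),
                   estimate = f$beta_refit,
                   shrunken = f$state$beta,
                   selected = f$support)
  }))
}

#' @export
glance.ar_path <- function(x, ...) {
  tibble::tibble(
    family = x$family, n_lambda = length(x$lambdas),
    lambda_min = min(x$lambdas), lambda_max = max(x$lambdas),
    size_min = min(x$support_sizes), size_max = max(x$support_sizes)
  )
}

#' @export
tidy.ar_segmentation <- function(x, ...) {
  seg <- segment_refit(x$y, x$breakpoints)
  tibble::tibble(segment = seq_along(seg$means), start = seg$starts,
                 end = seg$ends, mean = seg$means)
}

#' @export
glance.ar_segmentation <- function(x, ...) {
  tibble::tibble(
    n = length(x$y), lambda = x$lambda,
    n_breakpoints = length(x$breakpoints),
    iterations = x$state$iteration, converged = x$state$converged
  )
}

#' @export
tidy.dp_segmentation <- function(x, ...) {
  seg <- segment_refit(x$y, x$breakpoints)
  tibble::tibble(segment = seq_along(seg$means), start = seg$starts,
                 end = seg$ends, mean = seg$means)
}

#' @export
glance.dp_segmentation <- function(x, ...) {
  tibble::tibble(n = length(x$y), lambda = x$lambda,
                 n_breakpoints = length(x$breakpoints),
                 rss = x$rss, objective = x$objective)
}

#' @export
tidy.ar_model_fit <- function(x, ...) {
  tibble::tibble(term = which(x$support), estimate = x$coefficients[x$support])
}

#' @export
glance.ar_model_fit <- function(x, ...) {
  tibble::tibble(n_selected = x$size, minus2loglik = x$minus2loglik,
                 penalty = x$penalty, criterion = x$criterion)
}
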