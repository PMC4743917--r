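# Seed-deterministic generators for the simulation scenarios studied in the
# vignette, plus the benchmark harness computing power/FP/FDR/Mis summaries.

# Derived per-replicate seed kept below 2^31.
replicate_seed <- function(base_seed, r) {
  as.integer(((as.numeric(base_seed) %% 1000003) * 2011 + 7 * as.numeric(r)) %%
               2147483647)
}

#' Simulate correlated Gaussian regression data
#'
#' Rows of `X` are drawn from a zero-mean Gaussian with unit variances and
#' either compound-symmetry correlation (\eqn{\Sigma_{ij} = \rho}, all pairs)
#' or AR(1) correlation (\eqn{\Sigma_{ij} = \rho^{|i-j|}}); then
#' \eqn{y = X\beta + \varepsilon}, \eqn{\varepsilon \sim N(0, \sigma^2)}.
#' Defaults reproduce the small-p study conditions: `n = 50`, `p = 15`, five
#' effects of 0.5 on the first five coordinates, \eqn{\sigma = 1}.
#'
#' @param n,p Dimensions.
#' @param rho Pairwise correlation in `[0, 1)`.
#' @param corr `"cs"` (compound symmetry) or `"ar1"`.
#' @param support True-support indices (default `1:5`; the neighboring-pairs
#'   variant uses `c(2, 5, 8, 11, 14)`).
#' @param beta Common effect size of the true regressors (default 0.5).
#' @param sigma Noise standard deviation.
#' @param seed RNG seed.
#' @return A list `X`, `y`, `beta` (full vector), `support`.
#' @export
sim_correlated <- function(n = 50, p = 15, rho = 0, corr = c("cs", "ar1"),
                           support = 1:5, beta = 0.5, sigma = 1, seed = NULL) {
  corr <- match.arg(corr)
  stopifnot(rho >= 0, rho < 1, sigma > 0, all(support >= 1), all(support <= p))
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- if (rho == 0) Z else {
    Sigma <- if (corr == "cs") matrix(rho, p, p) + diag(1 - rho, p)
             else rho^abs(outer(seq_len(p), seq_len(p), "-"))
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("correlation matrix is not positive definite")
    Z %*% chol(Sigma)
  }
  b <- numeric(p)
  b[support] <- beta
  y <- drop(X %*% b) + sigma * rnorm(n)
  list(X = X, y = y, beta = b, support = sort(unique(as.integer(support))))
}

#' Simulate high-dimensional sparse Gaussian regression data
#'
#' Independent standard-normal regressors with a fixed-size random-effect
#' support: `n = 100`, `k = 24` true effects drawn \eqn{N(0, 0.5)} (variance
#' 0.5), \eqn{\sigma = 1}, with `p` ranging up to many times `n`.
#'
#' @param n,p Dimensions.
#' @param k True support size (placed on the first `k` coordinates).
#' @param beta_var Variance of the nonzero effects.
#' @param sigma Noise standard deviation.
#' @param seed RNG seed.
#' @return A list `X`, `y`, `beta`, `support`.
#' @export
sim_highdim <- function(n = 100, p = 500, k = 24, beta_var = 0.5,
                        sigma = 1, seed = NULL) {
  stopifnot(k <= p, sigma > 0, beta_var > 0)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- numeric(p)
  b[seq_len(k)] <- rnorm(k, sd = sqrt(beta_var))
  y <- drop(X %*% b) + sigma * rnorm(n)
  list(X = X, y = y, beta = b, support = seq_len(k))
}

#' Simulate weak-effect regression data (Gaussian or Poisson)
#'
#' Covariates \eqn{X_{ij} \sim N(0, 0.1^2)} and nonzero coefficients
#' \eqn{\beta_j \sim N(0, 1.5^2)} on the first `k` coordinates; with
#' `family = "gaussian"`, \eqn{y = X\beta + N(0, \sigma^2)} (noise sd 1 by
#' default — an assumption, see the vignette); with `family = "poisson"`,
#' \eqn{y_i \sim \mathrm{Poisson}(\exp(X_i\beta))}. Defaults: `n = 300` with
#' `p = 50`, `k = 10` (the `p = 500`, `k = 25` variant is selected by
#' arguments).
#'
#' @param n,p Dimensions.
#' @param k True support size.
#' @param x_sd Covariate standard deviation (0.1).
#' @param beta_sd Effect standard deviation (1.5).
#' @param family `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise sd.
#' @param seed RNG seed.
#' @return A list `X`, `y`, `beta`, `support`.
#' @export
sim_weak_effects <- function(n = 300, p = 50, k = 10, x_sd = 0.1,
                             beta_sd = 1.5, family = c("gaussian", "poisson"),
                             sigma = 1, seed = NULL) {
  family <- match.arg(family)
  stopifnot(k <= p, x_sd > 0, beta_sd > 0)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p, sd = x_sd), n, p)
  b <- numeric(p)
  b[seq_len(k)] <- rnorm(k, sd = beta_sd)
  eta <- drop(X %*% b)
  y <- if (family == "gaussian") eta + sigma * rnorm(n) else rpois(n, exp(eta))
  list(X = X, y = y, beta = b, support = seq_len(k), family = family)
}

#' Simulate a piecewise-constant signal with Gaussian noise
#'
#' Defaults reproduce the segmentation study conditions: `n = 500`,
#' breakpoints after positions 100, 250, 375, segment means
#' (-0.3, 0.7, 1.5, 0.5), noise sd 1.
#'
#' @param n Signal length.
#' @param breakpoints 1-based indices after which the mean changes.
#' @param means Segment means (length = breakpoints + 1).
#' @param sigma Noise sd.
#' @param seed RNG seed.
#' @return A list `y`, `mean` (noiseless step function), `breakpoints`,
#'   `means`.
#' @export
sim_step_signal <- function(n = 500, breakpoints = c(100, 250, 375),
                            means = c(-0.3, 0.7, 1.5, 0.5), sigma = 1,
                            seed = NULL) {
  stopifnot(length(means) == length(breakpoints) + 1L,
            all(diff(breakpoints) > 0), all(breakpoints >= 1),
            all(breakpoints < n), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  lens <- diff(c(0L, as.integer(breakpoints), n))
  mu <- rep(means, times = lens)
  list(y = mu + sigma * rnorm(n), mean = mu,
       breakpoints = as.integer(breakpoints), means = means)
}

#' Per-replicate selection metrics
#'
#' @param selected Selected index set (integer vector or logical mask).
#' @param truth True support (integer indices).
#' @param k_star True support size (defaults to `length(truth)`).
#' @return A [tibble::tibble] with one row: `tp`, `power`, `fp`, `fdr`,
#'   `mis`. FDR at an empty selection is 0.
#' @export
#' @examples
#' selection_metrics(c(1, 2, 3, 6), 1:5)
selection_metrics <- function(selected, truth, k_star = length(truth)) {
  if (is.logical(selected)) selected <- which(selected)
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  tibble::tibble(
    tp = tp,
    power = if (k_star > 0) tp / k_star else NA_real_,
    fp = fp,
    fdr = fp / max(1L, length(selected)),
    mis = (k_star - tp) + fp
  )
}

#' Run a replicated selection benchmark
#'
#' Per replicate, generates one dataset and applies each method to it;
#' aggregates power, false positives, FDR, misclassifications, the mean
#' squared criterion gap to the per-replicate best method (`mse_crit`), and
#' the fraction of replicates in which each method attains the minimal
#' criterion (`best_frac`, ties counting for all tied methods).
#'
#' @param generator A function `(seed) -> list(X, y, support, ...)`.
#' @param methods Named list of functions `(data) -> list(selected =
#'   indices-or-mask, criterion = scalar)`. A method may also return an
#'   `"ar_model_fit"`.
#' @param reps Number of replicates.
#' @param seed Base seed; replicate `r` uses a seed derived from it, so any
#'   subset of replicates is reproducible independently.
#' @param k_star True support size (defaults per replicate to
#'   `length(data$support)`).
#' @return A list: `summary` (tibble, one row per method: means plus
#'   standard errors of power and mis), `replicates` (tibble of
#'   per-replicate metrics), `failures` (count of failed method runs,
#'   excluded from aggregation).
#' @export
run_benchmark <- function(generator, methods, reps = 100, seed = 1,
                          k_star = NULL) {
  stopifnot(is.function(generator), length(methods) >= 1L,
            !is.null(names(methods)), reps >= 1)
  rows <- list()
  failures <- 0L
  for (r in seq_len(reps)) {
    dat <- generator(replicate_seed(seed, r))
    ks <- if (is.null(k_star)) length(dat$support) else k_star
    for (m in names(methods)) {
      res <- tryCatch(methods[[m]](dat), error = function(e) NULL)
      if (is.null(res)) { failures <- failures + 1L; next }
      if (inherits(res, "ar_model_fit"))
        res <- list(selected = which(res$support), criterion = res$criterion)
      met <- selection_metrics(res$selected, dat$support, ks)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r, method = m, criterion = res$criterion, met)
    }
  }
  repl <- do.call(rbind, rows)
  # criterion gap to the per-replicate best across methods
  best <- tapply(repl$criterion, repl$replicate, min)
  repl$crit_gap <- repl$criterion - as.numeric(best[as.character(repl$replicate)])
  repl$is_best <- repl$crit_gap <= 1e-8
  agg <- lapply(split(repl, repl$method), function(d) {
    tibble::tibble(
      method = d$method[1], reps = nrow(d),
      power = mean(d$power), power_se = sd(d$power) / sqrt(nrow(d)),
      fp = mean(d$fp), fdr = mean(d$fdr),
      mis = mean(d$mis), mis_se = sd(d$mis) / sqrt(nrow(d)),
      mse_crit = mean(d$crit_gap^2), best_frac = mean(d$is_best))
  })
  summary <- do.call(rbind, agg)[match(names(methods),
                                       vapply(agg, `[[`, character(1), "method")), ]
  list(summary = summary, replicates = repl, failures = failures)
}
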