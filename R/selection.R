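#' Model-selection criterion specification
#'
#' Defines a per-parameter L0 penalty: 2 for AIC, \eqn{\log n} for BIC, and
#' \eqn{\log(n\, p_{\mathrm{total}}^2 / c^2)} for the modified BIC
#' \eqn{\mathrm{mBIC}(c)} designed for sparse high-dimensional (GWAS-style)
#' selection, where `c` is the a-priori expected number of true regressors.
#'
#' For Gaussian problems with known variance the criterion is
#' \eqn{\mathrm{RSS}(M)/\sigma^2 + |M|\,\lambda_{\mathrm{crit}}}; with
#' `variance = "estimated"` it is \eqn{n \log(\mathrm{RSS}(M)/n) +
#' |M|\,\lambda_{\mathrm{crit}}}. For Poisson problems it is \eqn{-2\ell(M) +
#' |M|\,\lambda_{\mathrm{crit}}} with the refit log-likelihood of
#' [poisson_loglik()] (additive constants dropped; only differences are
#' meaningful).
#'
#' `p_total` defaults to the problem's column count but should stay at the
#' ORIGINAL regressor count when columns were removed by
#' [marginal_preselect()]: preselection is part of the search, not of the
#' model space the mBIC penalty prices.
#'
#' @param name `"aic"`, `"bic"` or `"mbic"`.
#' @param c Prior expected number of true regressors (mBIC only).
#' @param p_total Total regressor count for the mBIC penalty (see above).
#' @param variance `"known"` (uses the problem's `sigma2`) or `"estimated"`.
#' @return An object of class `"ar_criterion"`.
#' @export
#' @examples
#' criterion("mbic", c = 4, p_total = 1000)
criterion <- function(name = c("bic", "aic", "mbic"), c = 4, p_total = NULL,
                      variance = c("known", "estimated")) {
  name <- match.arg(name)
  variance <- match.arg(variance)
  stopifnot(c >= 1)
  if (!is.null(p_total)) stopifnot(p_total >= 1)
  structure(list(name = name, c = c, p_total = p_total, variance = variance),
            class = "ar_criterion")
}

#' @export
print.ar_criterion <- function(x, ...) {
  extra <- if (x$name == "mbic")
    sprintf(" (c = %g, p_total = %s)", x$c,
            if (is.null(x$p_total)) "problem p" else format(x$p_total)) else ""
  cat(sprintf("Selection criterion: %s%s, variance %s\n",
              toupper(x$name), extra, x$variance))
  invisible(x)
}

# Per-parameter penalty lambda_crit for a given problem size.
criterion_penalty <- function(spec, n, p) {
  p_total <- if (is.null(spec$p_total)) p else spec$p_total
  switch(spec$name,
         aic = 2,
         bic = log(n),
         mbic = log(n * p_total^2 / spec$c^2))
}

#' Evaluate a selection criterion at a support (by ML refit)
#'
#' Refits maximum likelihood on the given support and returns the criterion
#' value \eqn{-2\log L(M) + |M|\,\lambda_{\mathrm{crit}}}. Criteria are always
#' evaluated at the refit, never at shrunken adaptive ridge coefficients.
#'
#' @param problem A [linear_problem()] or [poisson_problem()].
#' @param support Logical mask or integer index vector of selected columns.
#' @param spec An [criterion()] specification.
#' @return A list of class `"ar_model_fit"`: `support` (logical),
#'   `coefficients`, `minus2loglik`, `criterion`, `penalty`, `size`.
#' @export
evaluate_criterion <- function(problem, support, spec = criterion()) {
  p <- problem$p
  if (is.logical(support)) {
    stopifnot(length(support) == p)
  } else {
    idx <- as.integer(support)
    stopifnot(all(idx >= 1L), all(idx <= p))
    support <- seq_len(p) %in% idx
  }
  size <- sum(support)
  if (size >= problem$n) stop("support size must be smaller than n for a refit")
  lam <- criterion_penalty(spec, problem$n, p)
  if (inherits(problem, "linear_problem")) {
    refit <- ols_refit(problem, support)
    m2l <- if (spec$variance == "known") refit$rss / problem$sigma2
           else problem$n * log(refit$rss / problem$n)
    coefs <- refit$beta
  } else if (inherits(problem, "poisson_problem")) {
    refit <- poisson_refit(problem, support)
    m2l <- -2 * refit$loglik
    coefs <- refit$beta
  } else stop("unsupported problem type")
  structure(
    list(support = support, coefficients = coefs, minus2loglik = m2l,
         criterion = m2l + size * lam, penalty = lam, size = size),
    class = "ar_model_fit"
  )
}

#' @export
print.ar_model_fit <- function(x, ...) {
  cat(sprintf("Model fit: |M| = %d {%s}, -2logL = %.4g, criterion = %.4g\n",
              x$size, paste(which(x$support), collapse = ", "),
              x$minus2loglik, x$criterion))
  invisible(x)
}

#' Choose the best model along a regularization path
#'
#' Evaluates the criterion at every *distinct* support on the path (each
#' support refit once) and returns the minimizer. Ties are broken toward
#' smaller supports, then larger penalties.
#'
#' @param path An `"ar_path"` from [ar_lm_path()] or [ar_poisson_path()].
#' @param spec A [criterion()].
#' @return An `"ar_model_fit"` with an extra `lambda` element (the smallest
#'   of the largest path penalties attaining the chosen support).
#' @export
choose_on_path <- function(path, spec = criterion()) {
  stopifnot(inherits(path, "ar_path"), length(path$fits) >= 1L)
  keys <- vapply(path$fits, function(f) paste(which(f$support), collapse = ","),
                 character(1))
  first <- !duplicated(keys)
  cand <- which(first)
  fits <- lapply(cand, function(i)
    evaluate_criterion(path$problem, path$fits[[i]]$support, spec))
  crit <- vapply(fits, `[[`, numeric(1), "criterion")
  size <- vapply(fits, `[[`, integer(1), "size")
  # best largest-lambda occurrence of each distinct support
  lam_last <- vapply(cand, function(i) max(path$lambdas[keys == keys[i]]),
                     numeric(1))
  ord <- order(crit, size, -lam_last)
  best <- fits[[ord[1]]]
  best$lambda <- lam_last[ord[1]]
  best
}

#' Exhaustive all-subset selection
#'
#' Minimizes the criterion over all \eqn{2^p} supports (Gaussian problems;
#' guarded to `p <= 20`). The enumeration runs in compiled code on the
#' precomputed Gram matrix.
#'
#' @param problem A [linear_problem()].
#' @param spec A [criterion()] (with `variance = "known"`).
#' @return An `"ar_model_fit"`.
#' @export
all_subset_select <- function(problem, spec = criterion()) {
  stopifnot(inherits(problem, "linear_problem"))
  if (problem$p > 20L)
    stop("all-subset selection is limited to p <= 20; use stepwise_select()")
  if (spec$variance != "known")
    stop("all_subset_select supports only the known-variance criterion form")
  lam <- criterion_penalty(spec, problem$n, problem$p)
  res <- cpp_all_subset(crossprod(problem$X),
                        drop(crossprod(problem$X, problem$y)),
                        sum(problem$y^2), problem$sigma2, lam)
  evaluate_criterion(problem, as.logical(res$support), spec)
}

# Marginal per-column test statistics: absolute t (Gaussian) or score z
# (Poisson), optionally adjusting for forced-in columns.
marginal_stats <- function(problem, adjust = NULL) {
  X <- problem$X; y <- problem$y
  p <- problem$p
  if (!is.null(adjust) && length(adjust)) {
    Q <- qr.Q(qr(X[, adjust, drop = FALSE]))
    y <- y - Q %*% crossprod(Q, y)
    X <- X - Q %*% crossprod(Q, X)
  }
  if (inherits(problem, "linear_problem")) {
    vapply(seq_len(p), function(j) {
      xj <- X[, j]
      sxx <- sum(xj^2)
      if (sxx < 1e-12) return(0)
      b <- sum(xj * y) / sxx
      res <- y - xj * b
      df <- problem$n - 1 - length(adjust)
      s2 <- sum(res^2) / max(df, 1)
      abs(b) / sqrt(s2 / sxx)
    }, numeric(1))
  } else {
    # Poisson score test of beta_j = 0 against the null rate exp(offset)
    mu0 <- exp(problem$offset)
    vapply(seq_len(p), function(j) {
      xj <- X[, j]
      u <- sum(xj * (y - mu0))
      v <- sum(xj^2 * mu0)
      if (v < 1e-12) 0 else abs(u) / sqrt(v)
    }, numeric(1))
  }
}

#' Marginal preselection of regressors
#'
#' Ranks regressors by single-regressor test statistics (absolute t for
#' Gaussian, score z for Poisson) and keeps either the top `m` or all with
#' marginal p-value below `alpha`. Exactly one of `m`, `alpha` must be given.
#' The returned mapping indexes back into the full design, and any mBIC
#' penalty downstream should keep `p_total` at the original column count.
#'
#' @param problem A [linear_problem()] or [poisson_problem()].
#' @param m Number of columns to keep.
#' @param alpha Marginal p-value threshold.
#' @param adjust Optional indices of forced-in adjustment columns (always
#'   kept, and regressed out before ranking).
#' @return A list: `problem` (reduced, same class), `keep` (original column
#'   indices in the reduced order).
#' @export
marginal_preselect <- function(problem, m = NULL, alpha = NULL, adjust = NULL) {
  if (is.null(m) == is.null(alpha))
    stop("give exactly one of `m` or `alpha`")
  stats <- marginal_stats(problem, adjust = adjust)
  p <- problem$p
  if (!is.null(m)) {
    if (m > p) {
      warning("`m` exceeds p; keeping all columns")
      m <- p
    }
    ranked <- setdiff(order(stats, decreasing = TRUE), adjust)
    keep <- sort(unique(c(adjust, head(ranked, m))))
  } else {
    df <- problem$n - 1 - length(adjust)
    pvals <- if (inherits(problem, "linear_problem"))
      2 * pt(stats, df = max(df, 1), lower.tail = FALSE)
    else 2 * pnorm(stats, lower.tail = FALSE)
    keep <- sort(unique(c(adjust, which(pvals < alpha))))
  }
  reduced <- if (inherits(problem, "linear_problem")) {
    pr <- problem
    pr$X <- problem$X[, keep, drop = FALSE]
    pr$p <- length(keep)
    pr$centers <- problem$centers[keep]
    pr$scales <- problem$scales[keep]
    pr
  } else {
    pr <- problem
    pr$X <- problem$X[, keep, drop = FALSE]
    pr$p <- length(keep)
    pr
  }
  list(problem = reduced, keep = keep)
}

#' Stepwise model selection with marginal screening
#'
#' The baseline search: (1) rank regressors by marginal test statistics;
#' (2) start from the model of the top `min(top_m, p)` regressors; (3) greedy
#' backward elimination all the way down to one regressor, recording the
#' criterion at every visited model; (4) from the best visited model, greedy
#' forward addition over all `p` regressors until no improvement.
#'
#' @param problem A [linear_problem()] or [poisson_problem()].
#' @param spec A [criterion()].
#' @param top_m Initial screen size (default 40).
#' @return An `"ar_model_fit"`.
#' @export
stepwise_select <- function(problem, spec = criterion(), top_m = 40L) {
  p <- problem$p
  stats <- marginal_stats(problem)
  start <- head(order(stats, decreasing = TRUE), min(top_m, p, problem$n - 2L))
  crit_of <- function(idx) evaluate_criterion(problem, idx, spec)$criterion
  best_crit <- Inf; best_set <- integer(0)
  note <- function(idx, value) {
    if (value < best_crit - 1e-12 ||
        (value <= best_crit + 1e-12 && length(idx) < length(best_set))) {
      best_crit <<- value; best_set <<- idx
    }
  }
  note(integer(0), crit_of(integer(0)))
  cur <- sort(start)
  note(cur, crit_of(cur))
  # backward elimination to size 1
  while (length(cur) > 1L) {
    vals <- vapply(seq_along(cur), function(k) crit_of(cur[-k]), numeric(1))
    k <- which.min(vals)
    cur <- cur[-k]
    note(cur, vals[k])
  }
  # forward from the best visited model
  cur <- best_set
  repeat {
    cand <- setdiff(seq_len(p), cur)
    if (!length(cand) || length(cur) >= problem$n - 2L) break
    vals <- vapply(cand, function(j) crit_of(sort(c(cur, j))), numeric(1))
    k <- which.min(vals)
    if (vals[k] < best_crit - 1e-12) {
      cur <- sort(c(cur, cand[k]))
      note(cur, vals[k])
    } else break
  }
  evaluate_criterion(problem, best_set, spec)
}
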