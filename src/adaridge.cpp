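// Compiled kernels: exhaustive best-subset search, the Newton solver for
// weighted-ridge Poisson regression, the O(n) smoothing recursion on first
// differences, and the O(kmax * n^2) exact segmentation DP.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exhaustive minimization of RSS/sigma2 + |M| * lambda_crit over all 2^p
// supports. Ties broken toward smaller |M|, then lexicographically smaller
// support. Returns the winning mask, its criterion and RSS.
// [[Rcpp::export]]
List cpp_all_subset(const arma::mat& XtX, const arma::vec& Xty,
                    double yty, double sigma2, double lambda_crit) {
  const int p = XtX.n_rows;
  if (p > 25) stop("all-subset enumeration limited to p <= 25");
  const unsigned long long nmask = 1ULL << p;

  double best_crit = yty / sigma2;  // empty model: RSS = y'y
  unsigned long long best_mask = 0ULL;
  int best_size = 0;
  double best_rss = yty;

  std::vector<arma::uword> idx;
  idx.reserve(p);
  for (unsigned long long mask = 1; mask < nmask; ++mask) {
    idx.clear();
    for (int j = 0; j < p; ++j)
      if (mask & (1ULL << j)) idx.push_back(j);
    const int k = (int)idx.size();
    arma::uvec ii(idx.data(), k, false);
    arma::mat A = XtX.submat(ii, ii);
    arma::vec b = Xty.elem(ii);
    arma::vec beta;
    bool ok = arma::solve(beta, A, b, arma::solve_opts::likely_sympd);
    if (!ok) continue;
    double rss = yty - arma::dot(b, beta);
    if (rss < 0) rss = 0;
    double crit = rss / sigma2 + k * lambda_crit;
    bool better = false;
    if (crit < best_crit - 1e-12) {
      better = true;
    } else if (crit <= best_crit + 1e-12) {
      if (k < best_size) better = true;
      else if (k == best_size && mask < best_mask) better = true;
    }
    if (better) {
      best_crit = crit; best_mask = mask; best_size = k; best_rss = rss;
    }
  }

  LogicalVector sel(p);
  for (int j = 0; j < p; ++j) sel[j] = (best_mask >> j) & 1ULL;
  return List::create(_["support"] = sel, _["criterion"] = best_crit,
                      _["rss"] = best_rss, _["size"] = best_size);
}

static double pois_penlik(const arma::mat& X, const arma::vec& y,
                          const arma::vec& beta, double lam,
                          const arma::vec& w, arma::vec& mu) {
  arma::vec eta = X * beta;
  if (eta.max() > 700.0) return -arma::datum::inf;  // exp overflow guard
  mu = arma::exp(eta);
  return arma::dot(beta, X.t() * y) - arma::accu(mu)
       - 0.5 * lam * arma::dot(w, arma::square(beta));
}

// Newton-Raphson with step halving for the weighted-ridge Poisson
// log-likelihood l(beta) = beta'X'y - 1'exp(X beta) - (lam/2) beta'diag(w)beta.
// [[Rcpp::export]]
List cpp_poisson_ridge(const arma::mat& X, const arma::vec& y, double lam,
                       const arma::vec& w, const arma::vec& beta0,
                       double grad_tol = 1e-8, int max_newton = 100) {
  arma::vec beta = beta0;
  arma::vec mu;
  double ll = pois_penlik(X, y, beta, lam, w, mu);
  if (!std::isfinite(ll)) { beta.zeros(); ll = pois_penlik(X, y, beta, lam, w, mu); }
  const arma::vec Xty = X.t() * y;
  bool converged = false;
  int it = 0;
  for (; it < max_newton; ++it) {
    arma::vec grad = Xty - X.t() * mu - lam * (w % beta);
    if (arma::abs(grad).max() < grad_tol) { converged = true; break; }
    arma::mat H = X.t() * (X.each_col() % mu);
    H.diag() += lam * w;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!ok) stop("singular Hessian in the Poisson Newton solver");
    // step-halving: accept the first step that does not decrease the objective
    double t = 1.0;
    bool accepted = false;
    for (int h = 0; h < 50; ++h) {
      arma::vec cand = beta + t * step;
      arma::vec mu_c;
      double ll_c = pois_penlik(X, y, cand, lam, w, mu_c);
      if (std::isfinite(ll_c) && ll_c >= ll - 1e-12) {
        beta = cand; ll = ll_c; mu = mu_c; accepted = true; break;
      }
      t *= 0.5;
    }
    if (!accepted) break;  // no ascent possible: at numerical optimum
  }
  return List::create(_["beta"] = beta, _["iterations"] = it,
                      _["converged"] = converged, _["penlik"] = ll);
}

// Exact O(n) minimizer of sum_i (y_i - mu_i)^2 + lam * sum_i w_i
// (mu_{i+1} - mu_i)^2 via the forward recursion mu_i = a_i + b_i mu_{i+1}
// and back-substitution.
// [[Rcpp::export]]
NumericVector cpp_weighted_smooth(const NumericVector& y, double lam,
                                  const NumericVector& w) {
  const int n = y.size();
  if (w.size() != n - 1) stop("`weights` must have length n - 1");
  if (n == 1) return clone(y);
  std::vector<double> a(n - 1), b(n - 1);
  double lw = lam * w[0];
  a[0] = y[0] / (1.0 + lw);
  b[0] = lw / (1.0 + lw);
  for (int i = 1; i < n - 1; ++i) {
    double lwi = lam * w[i], lwp = lam * w[i - 1];
    double D = 1.0 + lwi + lwp * (1.0 - b[i - 1]);
    a[i] = (y[i] + lwp * a[i - 1]) / D;
    b[i] = lwi / D;
  }
  NumericVector mu(n);
  double lwp = lam * w[n - 2];
  mu[n - 1] = (y[n - 1] + lwp * a[n - 2]) / (1.0 + lwp * (1.0 - b[n - 2]));
  for (int i = n - 2; i >= 0; --i) mu[i] = a[i] + b[i] * mu[i + 1];
  return mu;
}

// Exact L0 segmentation: minimize RSS + lambda * (#segments - 1) over all
// segmentations with at most kmax segments, by the classical k-segment DP on
// prefix-sum segment costs. Ties prefer fewer segments, then leftmost
// breakpoints. Breakpoints are 1-based "change after index i".
// [[Rcpp::export]]
List cpp_dp_segment(const NumericVector& y, double lambda, int kmax) {
  const int n = y.size();
  if (kmax < 1 || kmax > n) stop("`kmax` must be in 1..n");
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + y[i];
    S2[i + 1] = S2[i] + y[i] * y[i];
  }
  auto cost = [&](int i, int j) {  // RSS of one segment over y[i..j], 0-based
    double s = S[j + 1] - S[i];
    return S2[j + 1] - S2[i] - s * s / (j - i + 1);
  };

  // F[j]: best RSS covering 0..j with the current number of segments.
  std::vector<double> Fprev(n), Fcur(n);
  // back[k][j]: start index of the last segment in the best k-segmentation of 0..j
  std::vector<std::vector<int>> back(kmax, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) Fprev[j] = cost(0, j);
  std::vector<double> best_rss_k(kmax);
  best_rss_k[0] = Fprev[n - 1];

  for (int k = 2; k <= kmax; ++k) {
    for (int j = k - 1; j < n; ++j) {
      double best = arma::datum::inf;
      int arg = k - 1;
      for (int i = k - 1; i <= j; ++i) {
        double v = Fprev[i - 1] + cost(i, j);
        if (v < best - 1e-12) { best = v; arg = i; }
      }
      Fcur[j] = best;
      back[k - 1][j] = arg;
    }
    for (int j = 0; j < k - 1; ++j) Fcur[j] = arma::datum::inf;
    best_rss_k[k - 1] = Fcur[n - 1];
    std::swap(Fprev, Fcur);
  }

  int kbest = 1;
  double obj = best_rss_k[0];
  for (int k = 2; k <= kmax; ++k) {
    double v = best_rss_k[k - 1] + lambda * (k - 1);
    if (v < obj - 1e-12) { obj = v; kbest = k; }
  }

  // Backtrack the kbest-segmentation.
  std::vector<int> bps;
  int j = n - 1;
  for (int k = kbest; k >= 2; --k) {
    int i = back[k - 1][j];
    bps.push_back(i);  // 1-based breakpoint "after index i" == 0-based start i
    j = i - 1;
  }
  std::sort(bps.begin(), bps.end());
  IntegerVector breakpoints(bps.begin(), bps.end());
  return List::create(_["breakpoints"] = breakpoints,
                      _["rss"] = best_rss_k[kbest - 1],
                      _["objective"] = obj, _["k"] = kbest);
}
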