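#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net in covariance-update form.
//
// Objective (per observation scaling):
//   (1/(2n)) ||y - X b||^2 + lambda * ( alpha ||b||_1 + (1-alpha)/2 ||b||_2^2 )
//
// Inputs are the sufficient statistics XtXn = X'X/n, Xtyn = X'y/n and
// ytyn = y'y/n, so a whole lambda path costs O(cycles * m^2) regardless of
// n. The residual correlations c_j = (1/n) x_j'(y - X b) are cached and
// updated incrementally when a coefficient moves, and cycling alternates
// between full passes and passes over the currently nonzero (active)
// coordinates, with convergence declared only when a full pass moves no
// coefficient by tol or more. Coordinates with XtXn(j,j) == 0
// (zero-variance columns, dropped upstream) are pinned at 0. Solutions are
// warm-started along the lambda path.
//
// [[Rcpp::export]]
List enet_path_cpp(NumericMatrix XtXn, NumericVector Xtyn, double ytyn,
                   int n, NumericVector lambdas, double alpha,
                   int maxIter, double tol) {
  const int m = Xtyn.size();
  const int K = lambdas.size();
  NumericMatrix betas(m, K);
  NumericVector rss(K);
  LogicalVector converged(K);

  std::vector<double> G(XtXn.begin(), XtXn.end());   // column-major m x m
  std::vector<double> xty(Xtyn.begin(), Xtyn.end());
  std::vector<double> beta(m, 0.0), c(m), diag(m);
  std::vector<char> active(m, 0);
  for (int j = 0; j < m; ++j) diag[j] = G[j * m + j];

  for (int k = 0; k < K; ++k) {
    const double lam = lambdas[k];
    const double l1 = lam * alpha;
    const double l2 = lam * (1.0 - alpha);

    // refresh the cached correlations from scratch (kills drift)
    for (int j = 0; j < m; ++j) {
      double s = xty[j];
      const double* col = &G[j * m];
      for (int q = 0; q < m; ++q) s -= col[q] * beta[q];
      c[j] = s;
      active[j] = beta[j] != 0.0;
    }

    // one coordinate update; returns |change|
    auto update = [&](int j) -> double {
      const double djj = diag[j];
      if (djj <= 0.0) return 0.0;
      const double z = c[j] + djj * beta[j];
      double bnew = 0.0;
      if (z > l1)       bnew = (z - l1) / (djj + l2);
      else if (z < -l1) bnew = (z + l1) / (djj + l2);
      const double d = bnew - beta[j];
      if (d != 0.0) {
        const double* col = &G[j * m];
        for (int q = 0; q < m; ++q) c[q] -= col[q] * d;
        // c[j] was updated with the full column including q = j; that is
        // exactly the definition of c (sum over all k), so nothing to fix.
        beta[j] = bnew;
        active[j] = bnew != 0.0;
      }
      return std::fabs(d);
    };

    bool ok = false;
    int it = 0;
    while (it < maxIter) {
      // full pass
      double maxDelta = 0.0;
      for (int j = 0; j < m; ++j) {
        const double d = update(j);
        if (d > maxDelta) maxDelta = d;
      }
      ++it;
      if (maxDelta < tol) { ok = true; break; }
      // active-set passes
      while (it < maxIter) {
        double mda = 0.0;
        for (int j = 0; j < m; ++j) {
          if (!active[j]) continue;
          const double d = update(j);
          if (d > mda) mda = d;
        }
        ++it;
        if (mda < tol) break;
      }
    }
    converged[k] = ok;

    // RSS/n = ytyn - b'xty - b'c   (since c = xty - G b)
    double q = ytyn;
    for (int j = 0; j < m; ++j) q -= beta[j] * (xty[j] + c[j]);
    if (q < 0.0) q = 0.0;
    rss[k] = q * static_cast<double>(n);
    for (int j = 0; j < m; ++j) betas(j, k) = beta[j];
  }
  return List::create(_["beta"] = betas, _["rss"] = rss,
                      _["converged"] = converged);
}
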