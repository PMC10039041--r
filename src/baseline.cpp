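#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Asymmetric penalized least-squares (Whittaker/AsLS) baseline estimate.
// Solves (W + lambda * D2' D2) z = W y with a second-difference penalty,
// iteratively reweighting: w_i = p where y_i > z_i (peak side), 1 - p below.
// The system matrix is pentadiagonal; solved by a banded LDL^T factorization
// in O(n) per iteration.
// [[Rcpp::export]]
NumericVector als_baseline_cpp(NumericVector y, double lambda, double p,
                               int maxit) {
  const int n = y.size();
  if (n < 3) stop("spectrum too short for baseline estimation");
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(y[i])) stop("non-finite intensities");

  // Pentadiagonal bands of lambda * D2'D2 (constant across iterations).
  std::vector<double> pd(n), pe(n > 1 ? n - 1 : 0), pf(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) {
    double d;
    if (i == 0 || i == n - 1) d = 1.0;
    else if (i == 1 || i == n - 2) d = (n >= 4) ? 5.0 : 4.0;
    else d = 6.0;
    pd[i] = lambda * d;
  }
  for (int i = 0; i + 1 < n; ++i) {
    double e = (i == 0 || i == n - 2) ? -2.0 : -4.0;
    pe[i] = lambda * e;
  }
  for (int i = 0; i + 2 < n; ++i) pf[i] = lambda * 1.0;

  std::vector<double> w(n, 1.0), z(n, 0.0);
  std::vector<double> D(n), l1(n, 0.0), l2(n, 0.0), u(n);

  for (int it = 0; it < maxit; ++it) {
    // Factor A = L D L^T, A pentadiagonal with diag pd + w, bands pe, pf.
    for (int i = 0; i < n; ++i) {
      double m = pd[i] + w[i];
      if (i >= 1) m -= D[i - 1] * l1[i - 1] * l1[i - 1];
      if (i >= 2) m -= D[i - 2] * l2[i - 2] * l2[i - 2];
      D[i] = m;
      if (i + 1 < n) {
        double t = pe[i];
        if (i >= 1) t -= D[i - 1] * l1[i - 1] * l2[i - 1];
        l1[i] = t / m;
      }
      if (i + 2 < n) l2[i] = pf[i] / m;
    }
    // Forward solve L u = W y.
    for (int i = 0; i < n; ++i) {
      double b = w[i] * y[i];
      if (i >= 1) b -= l1[i - 1] * u[i - 1];
      if (i >= 2) b -= l2[i - 2] * u[i - 2];
      u[i] = b;
    }
    for (int i = 0; i < n; ++i) u[i] /= D[i];
    // Back solve L^T z = u.
    for (int i = n - 1; i >= 0; --i) {
      double v = u[i];
      if (i + 1 < n) v -= l1[i] * z[i + 1];
      if (i + 2 < n) v -= l2[i] * z[i + 2];
      z[i] = v;
    }
    // Reweight; stop when the weight pattern is stable.
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double wi = (y[i] > z[i]) ? p : (1.0 - p);
      if (wi != w[i]) { w[i] = wi; ++changed; }
    }
    if (changed == 0) break;
  }
  return NumericVector(z.begin(), z.end());
}
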