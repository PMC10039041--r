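// 1-D convolution and max-pool primitives for the scorer networks.
//
// Feature maps of length L with C channels are n x (L*C) R matrices in
// position-fastest order: column (p, c) = p + c*L (0-based). For kernel tap
// j, the input positions j..j+Lout-1 of channel c are the contiguous columns
// c*L+j .. c*L+j+Lout-1, so the (n*Lout) x (k*Cin) im2col matrix is
// assembled from k*Cin contiguous block copies and the convolution is one
// dgemm against the (k*Cin) x Cout kernel matrix (rows ordered tap-fastest
// within channel: row index = j + c*k).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const arma::mat& Xm, arma::mat& Xcol, int n, int L,
                   int Cin, int k, int Lout) {
  for (int c = 0; c < Cin; ++c)
    for (int j = 0; j < k; ++j)
      std::memcpy(Xcol.colptr((size_t)c * k + j),
                  Xm.colptr((size_t)c * L + j),
                  sizeof(double) * (size_t)n * Lout);
}

// [[Rcpp::export]]
NumericMatrix conv_fwd_cpp(const NumericMatrix& X, const NumericMatrix& W,
                           const NumericVector& b, int L, int Cin, int k) {
  const int n = X.nrow();
  const int Lout = L - k + 1;
  const int Cout = W.ncol();
  const arma::mat Xm(const_cast<double*>(X.begin()), n, (size_t)L * Cin,
                     false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), (size_t)k * Cin, Cout,
                     false, true);
  arma::mat Xcol((size_t)n * Lout, (size_t)k * Cin);
  im2col(Xm, Xcol, n, L, Cin, k, Lout);
  arma::mat Yf = Xcol * Wm;
  for (int co = 0; co < Cout; ++co) Yf.col(co) += b[co];
  NumericMatrix out(n, Lout * Cout);
  std::memcpy(out.begin(), Yf.memptr(),
              sizeof(double) * (size_t)n * Lout * Cout);
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const NumericMatrix& X, const NumericMatrix& W,
                  const NumericMatrix& dY, int L, int Cin, int k) {
  const int n = X.nrow();
  const int Lout = L - k + 1;
  const int Cout = W.ncol();
  const arma::mat Xm(const_cast<double*>(X.begin()), n, (size_t)L * Cin,
                     false, true);
  const arma::mat Wm(const_cast<double*>(W.begin()), (size_t)k * Cin, Cout,
                     false, true);
  const arma::mat dYf(const_cast<double*>(dY.begin()), (size_t)n * Lout,
                      Cout, false, true);
  arma::mat Xcol((size_t)n * Lout, (size_t)k * Cin);
  im2col(Xm, Xcol, n, L, Cin, k, Lout);
  arma::mat dW = Xcol.t() * dYf;
  arma::rowvec db = arma::sum(dYf, 0);
  arma::mat dXcol = dYf * Wm.t();            // (n*Lout) x (k*Cin)
  arma::mat dX(n, (size_t)L * Cin, arma::fill::zeros);
  const size_t len = (size_t)n * Lout;
  for (int c = 0; c < Cin; ++c)
    for (int j = 0; j < k; ++j) {
      double* dst = dX.colptr((size_t)c * L + j);
      const double* src = dXcol.colptr((size_t)c * k + j);
      for (size_t q = 0; q < len; ++q) dst[q] += src[q];
    }
  NumericMatrix dXout(n, L * Cin);
  std::memcpy(dXout.begin(), dX.memptr(),
              sizeof(double) * (size_t)n * L * Cin);
  NumericMatrix dWout((size_t)k * Cin, Cout);
  std::memcpy(dWout.begin(), dW.memptr(),
              sizeof(double) * (size_t)k * Cin * Cout);
  return List::create(_["dX"] = dXout, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pool over position blocks of size m (tail positions dropped), with
// first-max argmax recorded for the backward pass.
// [[Rcpp::export]]
List pool_fwd_cpp(const NumericMatrix& X, int L, int C, int m) {
  const int n = X.nrow();
  const int Lm = L / m;
  NumericMatrix Y(n, Lm * C);
  IntegerMatrix take(n, Lm * C);
  const double* xp = X.begin();
  double* yp = Y.begin();
  int* tp = take.begin();
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < Lm; ++q) {
      const size_t ybase = (size_t)n * (q + (size_t)c * Lm);
      const size_t xbase = (size_t)n * ((size_t)q * m + (size_t)c * L);
      for (int i = 0; i < n; ++i) {
        double best = xp[xbase + i];
        int bt = 0;
        for (int t = 1; t < m; ++t) {
          double v = xp[xbase + (size_t)t * n + i];
          if (v > best) { best = v; bt = t; }
        }
        yp[ybase + i] = best;
        tp[ybase + i] = bt;
      }
    }
  return List::create(_["out"] = Y, _["take"] = take);
}

// [[Rcpp::export]]
NumericMatrix pool_bwd_cpp(const NumericMatrix& dY, const IntegerMatrix& take,
                           int L, int C, int m) {
  const int n = dY.nrow();
  const int Lm = L / m;
  NumericMatrix dX(n, L * C);
  const double* dp = dY.begin();
  const int* tp = take.begin();
  double* xp = dX.begin();
  for (int c = 0; c < C; ++c)
    for (int q = 0; q < Lm; ++q) {
      const size_t ybase = (size_t)n * (q + (size_t)c * Lm);
      const size_t xbase = (size_t)n * ((size_t)q * m + (size_t)c * L);
      for (int i = 0; i < n; ++i)
        xp[xbase + (size_t)tp[ybase + i] * n + i] = dp[ybase + i];
    }
  return dX;
}
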