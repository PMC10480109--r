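#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy of one series. Template length m, Chebyshev tolerance r
// (absolute units). Counts B = pairs of m-templates within r, A = same for
// m+1; both indexed over i in [0, n-m-1] so every m-template has an
// extension. Self-matches excluded by i < j. Degenerate rules: B == 0 -> 0;
// A == 0 -> log(B) (capped sentinel).
static double sampen_one(const double* x, int n, int m, double r) {
  if (n <= m + 1) Rcpp::stop("sample entropy needs length > m + 1");
  long long A = 0, B = 0;
  const int nm = n - m;
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) break;
      }
      if (d <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0) return 0.0;
  if (A == 0) return std::log((double)B);
  return std::log((double)B) - std::log((double)A);
}

// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  return sampen_one(x.begin(), x.size(), m, r);
}

// Column-wise sample entropy; r_abs is per-column absolute tolerance.
// [[Rcpp::export(name = ".sampen_cols_cpp")]]
NumericVector sampen_cols_cpp(NumericMatrix w, int m, NumericVector r_abs) {
  int nc = w.ncol();
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c)
    out[c] = sampen_one(&w(0, c), w.nrow(), m, r_abs[c]);
  return out;
}

// Higuchi fractal dimension, standard construction: for each k average the
// normalized curve length over the k offsets, then FD = -slope of
// ln L(k) vs ln k. Flat series (all L(k) == 0) returns 1 by convention.
static double higuchi_one(const double* x, int n, int kmax) {
  if (n < kmax + 1) Rcpp::stop("higuchi_fd needs length > kmax");
  std::vector<double> lnL, lnk;
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    int used = 0;
    for (int m0 = 0; m0 < k; ++m0) {
      int nmax = (n - 1 - m0) / k;
      if (nmax < 1) continue;
      double L = 0.0;
      for (int i = 1; i <= nmax; ++i)
        L += std::fabs(x[m0 + i * k] - x[m0 + (i - 1) * k]);
      L *= (double)(n - 1) / ((double)nmax * k * k);
      Lk += L;
      ++used;
    }
    if (used == 0) continue;
    Lk /= used;
    if (Lk <= 0.0) return 1.0;
    lnL.push_back(std::log(Lk));
    lnk.push_back(std::log((double)k));
  }
  // least-squares slope of lnL on lnk
  int p = lnk.size();
  double mx = 0, my = 0;
  for (int i = 0; i < p; ++i) { mx += lnk[i]; my += lnL[i]; }
  mx /= p; my /= p;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < p; ++i) {
    sxy += (lnk[i] - mx) * (lnL[i] - my);
    sxx += (lnk[i] - mx) * (lnk[i] - mx);
  }
  return -sxy / sxx;
}

// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector x, int kmax) {
  return higuchi_one(x.begin(), x.size(), kmax);
}

// [[Rcpp::export(name = ".higuchi_cols_cpp")]]
NumericVector higuchi_cols_cpp(NumericMatrix w, int kmax) {
  int nc = w.ncol();
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c)
    out[c] = higuchi_one(&w(0, c), w.nrow(), kmax);
  return out;
}
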