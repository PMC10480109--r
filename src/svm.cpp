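#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise squared Euclidean distances between rows of A (na x d) and
// rows of B (nb x d); returns na x nb.
static void sqdist(const NumericMatrix& A, const NumericMatrix& B,
                   std::vector<double>& out) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  out.assign((size_t)na * nb, 0.0);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      out[(size_t)i * nb + j] = s;
    }
  }
}

// [[Rcpp::export(name = ".rbf_kernel_cpp")]]
NumericMatrix rbf_kernel_cpp(NumericMatrix A, NumericMatrix B, double gamma) {
  std::vector<double> d2;
  sqdist(A, B, d2);
  int na = A.nrow(), nb = B.nrow();
  NumericMatrix K(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      K(i, j) = std::exp(-gamma * d2[(size_t)i * nb + j]);
  return K;
}

// Binary soft-margin SVM dual solved by SMO with maximal-violating-pair
// working-set selection (first-order, LIBSVM-style stopping criterion).
// K: precomputed kernel (n x n); y: +1/-1. Returns alpha, b, iterations.
// Deterministic: no randomness, fixed scan order.
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix K, IntegerVector y, double C,
                 double tol, int max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), f(n, 0.0); // f_i = sum_j a_j y_j K_ij
  int iter = 0;
  double m_up = 0, m_low = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // v_i = y_i - f_i ; select i = argmax over I_up, j = argmin over I_low
    int i = -1, j = -1;
    m_up = -HUGE_VAL; m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = (double)y[t] - f[t];
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (up && v > m_up) { m_up = v; i = t; }
      if (low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) break;

    double s = (double)y[i] * y[j];
    double L, H;
    if (s > 0) { // same sign
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    } else {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    // E_t = f_t - y_t
    double Ei = f[i] - (double)y[i], Ej = f[j] - (double)y[j];
    double aj_new = alpha[j] + (double)y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = alpha[i] + s * (alpha[j] - aj_new);
    double di = (ai_new - alpha[i]) * y[i];
    double dj = (aj_new - alpha[j]) * y[j];
    if (std::fabs(di) < 1e-15 && std::fabs(dj) < 1e-15) break;
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
    alpha[i] = ai_new;
    alpha[j] = aj_new;
  }
  // b from the KKT gap midpoint
  double b = (m_up + m_low) / 2.0;
  if (!R_FINITE(b)) b = 0.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter,
                      _["gap"] = m_up - m_low);
}

// Decision values f(x) = sum_i coef_i K(sv_i, x) + b with RBF kernel.
// [[Rcpp::export(name = ".rbf_decision_cpp")]]
NumericVector rbf_decision_cpp(NumericMatrix sv, NumericVector coef,
                               double b, NumericMatrix xnew, double gamma) {
  int ns = sv.nrow(), nx = xnew.nrow(), d = sv.ncol();
  NumericVector out(nx);
  for (int j = 0; j < nx; ++j) {
    double acc = b;
    for (int i = 0; i < ns; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = sv(i, k) - xnew(j, k);
        s += diff * diff;
      }
      acc += coef[i] * std::exp(-gamma * s);
    }
    out[j] = acc;
  }
  return out;
}

// Causal IIR filtering, direct form II transposed, with initial state zi
// (length max(len(a),len(b)) - 1). Returns filtered signal and final state.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
List iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                    NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  for (int i = 0; i < std::min((int)zi.size(), nz); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double yt = bb[0] * x[t] + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * x[t] + z[i + 1] - aa[i + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * x[t] - aa[nz] * yt;
    y[t] = yt;
  }
  return List::create(_["y"] = y,
                      _["zf"] = NumericVector(z.begin(), z.end()));
}
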