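#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kernel matrices -----------------------------------------------------------

// [[Rcpp::export(name = ".cpp_rbf_kernel")]]
NumericMatrix cpp_rbf_kernel(NumericMatrix X, NumericMatrix Y, double gamma) {
  int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("feature dimension mismatch");
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - Y(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-gamma * s);
    }
  }
  return K;
}

// [[Rcpp::export(name = ".cpp_linear_kernel")]]
NumericMatrix cpp_linear_kernel(NumericMatrix X, NumericMatrix Y) {
  int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("feature dimension mismatch");
  NumericMatrix K(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X(i, k) * Y(j, k);
      K(i, j) = s;
    }
  return K;
}

// [[Rcpp::export(name = ".cpp_poly_kernel")]]
NumericMatrix cpp_poly_kernel(NumericMatrix X, NumericMatrix Y,
                              double degree, double coef0) {
  NumericMatrix K = cpp_linear_kernel(X, Y);
  int n = K.nrow(), m = K.ncol();
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      K(i, j) = std::pow(K(i, j) + coef0, degree);
  return K;
}

// SMO solver for the soft-margin SVM dual ----------------------------------
//
// max  sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
// s.t. sum(alpha_i y_i) = 0, 0 <= alpha_i <= C
//
// Second-order working-set selection (maximal violating pair for i, best
// guaranteed-progress partner for j); terminates when the KKT gap
// m(alpha) - M(alpha) drops below tol.

// [[Rcpp::export(name = ".cpp_smo")]]
List cpp_smo(NumericMatrix K, NumericVector y, double C,
             double tol, int max_iter) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be square and match y");
  std::vector<double> alpha(n, 0.0), u(n, 0.0);
  int iter = 0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;
  const double eps_a = 1e-12 * C;  // at-bound tolerance

  for (iter = 0; iter < max_iter; ++iter) {
    // ygrad_t = y_t - u_t; KKT gap is max over I_up minus min over I_low
    int i = -1, j = -1;
    m_up = -1e300; m_low = 1e300;
    for (int t = 0; t < n; ++t) {
      double g = y[t] - u[t];
      bool in_up  = (y[t] > 0 && alpha[t] < C - eps_a) ||
                    (y[t] < 0 && alpha[t] > eps_a);
      bool in_low = (y[t] < 0 && alpha[t] < C - eps_a) ||
                    (y[t] > 0 && alpha[t] > eps_a);
      if (in_up && g > m_up)  { m_up = g;  i = t; }
      if (in_low && g < m_low) m_low = g;
    }
    if (i < 0 || m_up - m_low <= tol) { converged = true; break; }
    // partner: largest decrease of the dual objective among valid j
    double best_score = 0.0;
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] < 0 && alpha[t] < C - eps_a) ||
                    (y[t] > 0 && alpha[t] > eps_a);
      if (!in_low) continue;
      double g = y[t] - u[t];
      double b_it = m_up - g;
      if (b_it <= 0.0) continue;
      double a_it = K(i, i) + K(t, t) - 2.0 * K(i, t);
      if (a_it < 1e-12) a_it = 1e-12;
      double score = -(b_it * b_it) / a_it;
      if (score < best_score) { best_score = score; j = t; }
    }
    if (j < 0) { converged = true; break; }

    double s = y[i] * y[j];
    double Ei = u[i] - y[i], Ej = u[j] - y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double aj_new = alpha[j] + y[j] * (Ei - Ej) / eta;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    if (aj_new < eps_a) aj_new = 0.0;          // snap to the box
    if (aj_new > C - eps_a) aj_new = C;
    double dj = aj_new - alpha[j];
    if (std::fabs(dj) < 1e-14) break;  // numerically stalled
    double ai_new = alpha[i] + s * (alpha[j] - aj_new);
    if (ai_new < eps_a) ai_new = 0.0;
    if (ai_new > C - eps_a) ai_new = C;
    double di = ai_new - alpha[i];
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      u[t] += di * y[i] * K(t, i) + dj * y[j] * K(t, j);
  }

  // bias: average y_i - u_i over free support vectors, else KKT midpoint
  double b = 0.0; int nfree = 0;
  double eps_b = 1e-8 * C;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > eps_b && alpha[t] < C - eps_b) { b += y[t] - u[t]; ++nfree; }
  if (nfree > 0) b /= nfree; else b = 0.5 * (m_up + m_low);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = b,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}

// One-shot train + holdout accuracy with an RBF kernel. This is the hot
// path of the wrapper search: thousands of calls per nested-CV run.

// [[Rcpp::export(name = ".cpp_rbf_holdout_accuracy")]]
double cpp_rbf_holdout_accuracy(NumericMatrix Xtr, NumericVector ytr,
                                NumericMatrix Xte, NumericVector yte,
                                double gamma, double C, double tol,
                                int max_iter) {
  NumericMatrix K = cpp_rbf_kernel(Xtr, Xtr, gamma);
  List fit = cpp_smo(K, ytr, C, tol, max_iter);
  NumericVector alpha = fit["alpha"];
  double b = fit["bias"];
  int n = Xtr.nrow(), m = Xte.nrow(), d = Xtr.ncol();
  int correct = 0;
  for (int j = 0; j < m; ++j) {
    double f = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0.0) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = Xtr(i, k) - Xte(j, k);
        s += diff * diff;
      }
      f += alpha[i] * ytr[i] * std::exp(-gamma * s);
    }
    double pred = (f >= 0.0) ? 1.0 : -1.0;
    if (pred == yte[j]) ++correct;
  }
  return (double)correct / (double)m;
}

// Zero-phase IIR filtering --------------------------------------------------
//
// Applies the rational filter (b, a) forward then backward over each column,
// with odd-reflection padding at both ends to suppress start-up transients.

static void filt_inplace(const std::vector<double>& b,
                         const std::vector<double>& a,
                         std::vector<double>& x) {
  int n = x.size(), nb = b.size(), na = a.size();
  int order = std::max(nb, na) - 1;
  std::vector<double> z(order, 0.0);  // direct form II transposed state
  std::vector<double> bb(order + 1, 0.0), aa(order + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (order > 0 ? z[0] : 0.0);
    for (int k = 0; k < order - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (order > 0) z[order - 1] = bb[order] * xt - aa[order] * yt;
    x[t] = yt;
  }
}

// [[Rcpp::export(name = ".cpp_filtfilt")]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericMatrix X, int padlen) {
  int n = X.nrow(), nc = X.ncol();
  if (padlen >= n) padlen = n - 1;
  if (padlen < 0) padlen = 0;
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  if (av.empty() || av[0] == 0.0) stop("a[1] must be non-zero");
  if (av[0] != 1.0) {
    for (size_t i = 0; i < bv.size(); ++i) bv[i] /= av[0];
    for (size_t i = 0; i < av.size(); ++i) av[i] /= av[0];
  }
  NumericMatrix out(n, nc);
  int m = n + 2 * padlen;
  std::vector<double> w(m);
  for (int c = 0; c < nc; ++c) {
    // odd reflection: 2*x[0] - x[k] at the head, 2*x[n-1] - x[n-1-k] tail
    for (int k = 0; k < padlen; ++k) w[k] = 2.0 * X(0, c) - X(padlen - k, c);
    for (int t = 0; t < n; ++t) w[padlen + t] = X(t, c);
    for (int k = 0; k < padlen; ++k)
      w[padlen + n + k] = 2.0 * X(n - 1, c) - X(n - 2 - k, c);
    filt_inplace(bv, av, w);
    std::reverse(w.begin(), w.end());
    filt_inplace(bv, av, w);
    std::reverse(w.begin(), w.end());
    for (int t = 0; t < n; ++t) out(t, c) = w[padlen + t];
  }
  return out;
}
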