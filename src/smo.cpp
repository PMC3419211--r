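// Sequential minimal optimization for the soft-margin RBF C-SVM dual:
//   min 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
// with maximal-violating-pair working-set selection and the standard
// KKT-gap stopping rule. Problem sizes here are a few hundred rows, so
// the full kernel matrix is precomputed.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  for (int k = 0; k < X.ncol(); ++k) {
    double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List smo_fit(NumericMatrix X, NumericVector y, double C, double gamma,
             double tol = 1e-3, int max_iter = 100000) {
  const int n = X.nrow();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = rbf(X, i, j, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Q a - e
  const double beps = 1e-12 * (C > 1 ? C : 1.0);  // at-bound tolerance
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // i: argmax -y_t G_t over I_up = {y=+1, a<C} u {y=-1, a>0}
    // j: argmin -y_t G_t over I_low = {y=+1, a>0} u {y=-1, a<C}
    int i = -1, j = -1;
    m_up = -HUGE_VAL; m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < C - beps) || (y[t] < 0 && alpha[t] > beps);
      bool in_low = (y[t] > 0 && alpha[t] > beps) || (y[t] < 0 && alpha[t] < C - beps);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) break;

    // analytic two-variable update (Platt), E_t = y_t G_t
    double s = y[i] * y[j];
    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta < 1e-12) eta = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    double aj_new = aj + y[j] * (y[i] * G[i] - y[j] * G[j]) / eta;
    double L, H;
    if (s < 0) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else       { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = ai + s * (aj - aj_new);
    // snap to the box so bound membership stays exact
    if (aj_new < beps) aj_new = 0.0; else if (aj_new > C - beps) aj_new = C;
    if (ai_new < beps) ai_new = 0.0; else if (ai_new > C - beps) ai_new = C;
    double dai = ai_new - ai, daj = aj_new - aj;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) break;
    alpha[i] = ai_new; alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                      y[j] * K[(size_t)j * n + t] * daj);
  }

  // bias: average y_t - f_nb(x_t) over free SVs, else KKT-gap midpoint
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -y[t] * G[t]; // equals y_t - f_nb(x_t) at a free SV
      ++nfree;
    }
  }
  b = nfree > 0 ? b / nfree : 0.5 * (m_up + m_low);

  std::vector<int> sv;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-8) sv.push_back(t);
  NumericMatrix svx(sv.size(), X.ncol());
  NumericVector coef(sv.size());
  for (size_t r = 0; r < sv.size(); ++r) {
    coef[r] = alpha[sv[r]] * y[sv[r]];
    for (int k = 0; k < X.ncol(); ++k) svx(r, k) = X(sv[r], k);
  }
  return List::create(_["sv_x"] = svx, _["coef"] = coef, _["b"] = b,
                      _["iterations"] = iter, _["n_sv"] = (int)sv.size());
}

// decision values f(x) = sum_r coef_r K(sv_r, x) + b
// [[Rcpp::export]]
NumericVector rbf_decision(NumericMatrix sv_x, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int m = Xnew.nrow(), nsv = sv_x.nrow(), d = Xnew.ncol();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = b;
    for (int r = 0; r < nsv; ++r) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double df = Xnew(i, k) - sv_x(r, k);
        s += df * df;
      }
      acc += coef[r] * std::exp(-gamma * s);
    }
    out[i] = acc;
  }
  return out;
}
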