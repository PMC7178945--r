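#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// C-support vector classification on a precomputed kernel matrix, trained by
// sequential minimal optimization with maximal-violating-pair working-set
// selection.  Dual problem:
//   min 1/2 a' Q a - e' a,  Q_ts = y_t y_s K_ts,  0 <= a <= C,  y' a = 0.
// Deterministic: no randomness, ties resolved by the lowest index.
//
// Returns alpha, the bias b of the decision function
//   f(x) = sum_t alpha_t y_t K(x_t, x) + b   (label +1 iff f >= 0),
// and the number of pair updates performed.
// [[Rcpp::export]]
List smo_train(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel matrix / label size mismatch");
  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // gradient of the dual objective
  const double bound_tol = 1e-12;

  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: i maximizes -y*grad over I_up, j minimizes over I_low
    int i = -1, j = -1;
    m_up = -1e300; m_low = 1e300;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      const bool at_upper = alpha[t] >= C - bound_tol;
      const bool at_lower = alpha[t] <= bound_tol;
      const bool in_up  = (y[t] == 1 && !at_upper) || (y[t] == -1 && !at_lower);
      const bool in_low = (y[t] == 1 && !at_lower) || (y[t] == -1 && !at_upper);
      if (in_up && v > m_up)  { m_up = v;  i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    // two-variable analytic solution (Platt), with E_t = y_t * grad_t
    const double Ei = y[i] * grad[i];
    const double Ej = y[j] * grad[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;

    const double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    double aj_new = aj_old + y[j] * (Ei - Ej) / eta;
    if (aj_new > H) aj_new = H;
    if (aj_new < L) aj_new = L;
    const double ai_new = ai_old + y[i] * y[j] * (aj_old - aj_new);

    const double di = ai_new - ai_old, dj = aj_new - aj_old;
    if (std::abs(di) < 1e-14 && std::abs(dj) < 1e-14) break;  // numerically stuck
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t) {
      grad[t] += y[t] * (y[i] * K(t, i) * di + y[j] * K(t, j) * dj);
    }
  }

  // recompute the violation bounds at termination for the bias
  double gmax = -1e300, gmin = 1e300;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * grad[t];
    const bool at_upper = alpha[t] >= C - bound_tol;
    const bool at_lower = alpha[t] <= bound_tol;
    if (((y[t] == 1 && !at_upper) || (y[t] == -1 && !at_lower)) && v > gmax) gmax = v;
    if (((y[t] == 1 && !at_lower) || (y[t] == -1 && !at_upper)) && v < gmin) gmin = v;
  }
  double b;
  if (gmax <= -1e299 && gmin >= 1e299) b = 0.0;          // all bounded both ways
  else if (gmax <= -1e299) b = gmin;
  else if (gmin >= 1e299) b = gmax;
  else b = (gmax + gmin) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}
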