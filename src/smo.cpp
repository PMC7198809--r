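#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin SVM dual solved by sequential minimal optimization with
// maximal-violating-pair working-set selection:
//   min_a  0.5 a' Q a - e' a,  Q_ij = y_i y_j K_ij,
//   s.t.   0 <= a_i <= C,  sum_i y_i a_i = 0.
// Deterministic: zero initialisation, index-order tie breaking, no RNG.
// The bias b is averaged over free support vectors (0 < a < C); when none
// are free it is the midpoint of the KKT-feasible interval.
// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const NumericVector& y, double C,
               double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> a(n, 0.0), G(n, -1.0);  // G = Q a - e
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    int i = -1, j = -1;
    double Gmax = -INFINITY, Gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      const bool low = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin <= tol) { converged = true; break; }

    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    const double ai = a[i], aj = a[j];
    const double s = y[i] * y[j];
    // Unconstrained optimum along the pair direction (errors E_t = y_t G_t).
    double ajn = aj + y[j] * (y[i] * G[i] - y[j] * G[j]) / eta;
    double L, H;
    if (s < 0) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else       { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    if (ajn < L) ajn = L;
    if (ajn > H) ajn = H;
    double ain = ai + s * (aj - ajn);
    // snap to the box so floating-point residue never strands a multiplier
    // epsilon-inside a bound (which would stall the pair selection)
    const double snap = 1e-12 * std::max(1.0, C);
    if (ajn < snap) ajn = 0.0; else if (ajn > C - snap) ajn = C;
    if (ain < snap) ain = 0.0; else if (ain > C - snap) ain = C;
    const double dI = ain - ai, dJ = ajn - aj;
    if (std::fabs(dI) < 1e-16 && std::fabs(dJ) < 1e-16) break;  // stalled
    a[i] = ain; a[j] = ajn;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dI + y[j] * K(t, j) * dJ);
    ++iter;
  }

  // b from free support vectors, else KKT-interval midpoint.
  const double eps_b = 1e-10;
  double sum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (a[t] > eps_b && a[t] < C - eps_b) { sum += -y[t] * G[t]; ++nfree; }
  double b;
  if (nfree > 0) {
    b = sum / nfree;
  } else {
    double lo = -INFINITY, hi = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      const bool low = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
      if (up && v > lo) lo = v;
      if (low && v < hi) hi = v;
    }
    b = 0.5 * (lo + hi);
  }

  // Dual objective sum(a) - 0.5 a'Qa = 0.5 sum_t a_t (1 - G_t).
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * a[t] * (1.0 - G[t]);

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = iter, _["converged"] = converged);
}
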