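#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequential minimal optimization for the epsilon-SVR dual.
//
// The dual is written over 2n variables a = (alpha, alpha*) in [0, C]^{2n}
// with signs s = (+1,...,+1, -1,...,-1) and the equality constraint
// sum_t s_t a_t = 0:
//
//   min  1/2 a' Q a + p' a,   Q[t,u] = s_t s_u K[b(t), b(u)],
//   p = (eps - y, eps + y),   b(t) = t mod n.
//
// Working-set selection is second order: the first index maximizes the
// KKT violation over the "up" set, and the partner is chosen among
// violating "down" indices to maximize the guaranteed objective decrease
// b^2 / a (the LIBSVM WSS2 rule). The two-variable subproblem is solved
// analytically along the feasible direction d_i = s_i t, d_j = -s_j t
// (which preserves the equality constraint), with the near-zero-curvature
// case regularized by a small floor on a.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double epsilon,
               double tol, int max_iter) {
  const int n = y.size();
  const int N = 2 * n;
  std::vector<double> a(N, 0.0), G(N);
  for (int i = 0; i < n; ++i) {
    G[i] = epsilon - y[i];
    G[n + i] = epsilon + y[i];
  }
  const double bnd = 1e-12 * std::max(C, 1.0);
  const double tau = 1e-12;
  int iter = 0;
  double gap = R_PosInf;
  bool converged = false;

  while (iter < max_iter) {
    // first index: maximal violation over the up set
    int ii = -1;
    double mi = -R_PosInf, mj = R_PosInf;
    for (int t = 0; t < N; ++t) {
      const double s = (t < n) ? 1.0 : -1.0;
      const double m = -s * G[t];
      const bool can_up = (s > 0) ? (a[t] < C - bnd) : (a[t] > bnd);
      const bool can_dn = (s > 0) ? (a[t] > bnd) : (a[t] < C - bnd);
      if (can_up && m > mi) { mi = m; ii = t; }
      if (can_dn && m < mj) mj = m;
    }
    if (ii < 0 || mj == R_PosInf) { gap = 0.0; converged = true; break; }
    gap = mi - mj;
    if (gap < tol) { converged = true; break; }

    // second index: best guaranteed decrease among violating down indices
    const int bi = ii % n;
    const double si = (ii < n) ? 1.0 : -1.0;
    const double Kii = K(bi, bi);
    int jj = -1;
    double best = -R_PosInf;
    for (int t = 0; t < N; ++t) {
      const double s = (t < n) ? 1.0 : -1.0;
      const bool can_dn = (s > 0) ? (a[t] > bnd) : (a[t] < C - bnd);
      if (!can_dn) continue;
      const double m = -s * G[t];
      const double b = mi - m;
      if (b <= 0.0) continue;
      const int bt = t % n;
      double qa = Kii + K(bt, bt) - 2.0 * si * s * K(bi, bt);
      if (qa < tau) qa = tau;
      const double dec = b * b / qa;
      if (dec > best) { best = dec; jj = t; }
    }
    if (jj < 0) { converged = true; break; }

    const int bj = jj % n;
    const double sj = (jj < n) ? 1.0 : -1.0;
    double q = K(bi, bi) + K(bj, bj) - 2.0 * si * sj * K(bi, bj);
    if (q < tau) q = tau;
    const double g = si * G[ii] - sj * G[jj];  // dObj/dt, negative
    const double tmax_i = (si > 0) ? C - a[ii] : a[ii];
    const double tmax_j = (sj > 0) ? a[jj] : C - a[jj];
    const double tmax = std::min(tmax_i, tmax_j);
    double step = std::min(std::max(-g / q, 0.0), tmax);
    if (step <= 0.0) { converged = true; break; }

    const double di = si * step, dj = -sj * step;
    a[ii] += di;
    a[jj] += dj;
    const double wi = si * di, wj = sj * dj;
    for (int t = 0; t < N; ++t) {
      const int bt = (t < n) ? t : t - n;
      const double s = (t < n) ? 1.0 : -1.0;
      G[t] += s * (K(bt, bi) * wi + K(bt, bj) * wj);
    }
    ++iter;
  }

  NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = a[i] - a[n + i];
  return List::create(_["beta"] = beta,
                      _["iterations"] = iter,
                      _["kkt_gap"] = gap,
                      _["converged"] = converged);
}
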