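#include <Rcpp.h>
using namespace Rcpp;

// Pairwise working-set ascent on the dual of linear eps-insensitive SVR,
// in the beta = alpha - alpha* parametrization:
//
//   minimize  1/2 b'Kb + eps * sum|b_i| - y'b
//   subject to sum(b) = 0,  -C <= b_i <= C
//
// Each sample yields bounds on the bias multiplier from the KKT system
// (r_i = y_i - f_i, f = K b):
//   beta_i < C  =>  b >= L_i = r_i + eps (beta_i < 0) else r_i - eps
//   beta_i > -C =>  b <= U_i = r_i - eps (beta_i > 0) else r_i + eps
// The maximal-violating pair is (argmax L, argmin U); the two-variable
// subproblem along sum(b) = const is piecewise quadratic (breakpoints at
// beta_i + d = 0 and beta_j - d = 0) and is solved exactly.

// Exact minimizer of the convex piecewise-quadratic two-variable
// subproblem phi(d) = 1/2 eta d^2 + s0 d + eps(|bi+d|-|bi|) +
// eps(|bj-d|-|bj|) over d in [0, hi], found by walking the segment
// slopes (slopes are O(KKT violation), so this stays accurate where
// direct objective evaluation would cancel catastrophically).
static double solve_pair(double eta, double s0, double eps,
                         double bi, double bj, double hi) {
  std::vector<double> knots;
  knots.push_back(0.0);
  if (-bi > 0.0 && -bi < hi) knots.push_back(-bi);
  if (bj > 0.0 && bj < hi) knots.push_back(bj);
  knots.push_back(hi);
  std::sort(knots.begin(), knots.end());
  for (size_t k = 0; k + 1 < knots.size(); ++k) {
    const double a = knots[k], b = knots[k + 1];
    if (!(b > a)) continue;
    const double mid = 0.5 * (a + b);
    const double si = (bi + mid >= 0.0) ? 1.0 : -1.0;
    const double sj = (bj - mid >= 0.0) ? 1.0 : -1.0;
    const double lin = s0 + eps * (si - sj);
    if (eta * a + lin >= 0.0) return a;       // slope turned nonnegative
    if (eta > 0.0) {
      const double star = -lin / eta;
      if (star <= b) return star;             // interior stationary point
    }
  }
  return hi;
}

// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol, int max_iter) {
  const int n = y.size();
  std::vector<double> beta(n, 0.0), f(n, 0.0);
  const double snap = 1e-10 * std::max(1.0, C);
  double viol = R_PosInf;
  int iter = 0;
  bool stalled = false;

  for (iter = 0; iter < max_iter; ++iter) {
    int ilo = -1, iup = -1;
    double maxL = -R_PosInf, minU = R_PosInf;
    for (int i = 0; i < n; ++i) {
      const double r = y[i] - f[i];
      if (beta[i] < C) {
        const double L = (beta[i] < 0.0) ? r + eps : r - eps;
        if (L > maxL) { maxL = L; ilo = i; }
      }
      if (beta[i] > -C) {
        const double U = (beta[i] > 0.0) ? r - eps : r + eps;
        if (U < minU) { minU = U; iup = i; }
      }
    }
    viol = maxL - minU;
    if (!(viol > tol)) break;

    const int i = ilo, j = iup;
    const double bi = beta[i], bj = beta[j];
    const double hi = std::min(C - bi, bj + C);
    const double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    const double s0 = -((y[i] - f[i]) - (y[j] - f[j]));

    const double best_d = solve_pair(eta, s0, eps, bi, bj, hi);
    if (!(best_d > 0.0)) { stalled = true; break; }

    beta[i] = bi + best_d;
    beta[j] = bj - best_d;
    for (int k = 0; k < 2; ++k) {
      double &b = beta[k == 0 ? i : j];
      if (std::abs(b) < snap) b = 0.0;
      else if (std::abs(b - C) < snap) b = C;
      else if (std::abs(b + C) < snap) b = -C;
    }

    for (int k = 0; k < n; ++k) f[k] += best_d * (K(k, i) - K(k, j));
    if ((iter + 1) % 512 == 0) {  // periodic refresh against drift
      for (int k = 0; k < n; ++k) {
        double acc = 0.0;
        for (int l = 0; l < n; ++l) acc += K(k, l) * beta[l];
        f[k] = acc;
      }
    }
  }

  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["iterations"] = iter,
                      _["violation"] = viol,
                      _["stalled"] = stalled);
}
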