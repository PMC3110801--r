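#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft-margin C-SVC trained by sequential minimal optimization (Platt's
// algorithm with an error cache and second-choice heuristic).  The kernel
// matrix is precomputed by the caller; problem sizes here are a few hundred
// points, so the O(n^2) memory is cheap and the solver is exact enough at
// tol for sign-level decisions.

static inline bool non_bound(double a, double C) {
  return a > 1e-12 && a < C - 1e-12;
}

struct SmoState {
  const NumericMatrix &K;
  const NumericVector &y;
  double C, tol;
  std::vector<double> alpha, E;
  double b;
  long steps;

  SmoState(const NumericMatrix &K_, const NumericVector &y_, double C_, double tol_)
    : K(K_), y(y_), C(C_), tol(tol_), alpha(y_.size(), 0.0), E(y_.size()), b(0.0), steps(0) {
    for (int i = 0; i < y_.size(); ++i) E[i] = -y_[i];
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    double E1 = E[i1], E2 = E[i2];
    double L, H;
    if (y1 != y2) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (L >= H - 1e-12) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > 1e-12) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // objective value at the two clip bounds
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - s * a1 * k12 - a2 * k22;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double psiL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 + 0.5 * L * L * k22 + s * L * L1 * k12;
      double psiH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 + 0.5 * H * H * k22 + s * H * H1 * k12;
      if (psiL < psiH - 1e-12) a2new = L;
      else if (psiL > psiH + 1e-12) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < 1e-12 * (a2new + a2 + 1e-12)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    if (non_bound(a1new, C)) bnew = b1;
    else if (non_bound(a2new, C)) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    int n = y.size();
    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) + db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    ++steps;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if (!((r2 < -tol && a2 < C - 1e-12) || (r2 > tol && a2 > 1e-12))) return false;
    int n = y.size();
    // heuristic 1: maximize |E1 - E2| over non-bound points
    int best = -1;
    double bestgap = -1.0;
    for (int i = 0; i < n; ++i) {
      if (!non_bound(alpha[i], C)) continue;
      double gap = std::fabs(E[i] - E2);
      if (gap > bestgap) { bestgap = gap; best = i; }
    }
    if (best >= 0 && take_step(best, i2)) return true;
    // heuristic 2: all non-bound, fixed starting point for determinism
    for (int i = 0; i < n; ++i)
      if (non_bound(alpha[i], C) && take_step(i, i2)) return true;
    for (int i = 0; i < n; ++i)
      if (take_step(i, i2)) return true;
    return false;
  }
};

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol = 1e-3,
               double max_steps = 2e6) {
  SmoState st(K, y, C, tol);
  int n = y.size();
  int num_changed = 0;
  bool examine_all = true;
  while ((num_changed > 0 || examine_all) && st.steps < (long)max_steps) {
    num_changed = 0;
    if (examine_all) {
      for (int i = 0; i < n; ++i) num_changed += st.examine(i) ? 1 : 0;
    } else {
      for (int i = 0; i < n; ++i)
        if (non_bound(st.alpha[i], C)) num_changed += st.examine(i) ? 1 : 0;
    }
    if (examine_all) examine_all = false;
    else if (num_changed == 0) examine_all = true;
  }
  return List::create(_["alpha"] = NumericVector(st.alpha.begin(), st.alpha.end()),
                      _["b"] = st.b,
                      _["steps"] = (double)st.steps,
                      _["converged"] = st.steps < (long)max_steps);
}

// [[Rcpp::export(name = ".rbf_cross_kernel")]]
NumericMatrix rbf_cross_kernel(NumericMatrix A, NumericMatrix B, double gamma) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  NumericMatrix K(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-gamma * s);
    }
  }
  return K;
}
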