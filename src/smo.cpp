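#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual with a precomputed
// kernel matrix (Platt's algorithm with a full error cache and deterministic
// second-choice scanning, so repeated fits are bit-identical).
//
// minimize 1/2 sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
// s.t.     0 <= a_i <= C,  sum_i a_i y_i = 0

namespace {

struct Smo {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol, eps;
  int n;
  std::vector<double> alpha, E;  // E_i = f(x_i) - y_i, maintained incrementally
  double b;

  Smo(const NumericMatrix& K_, const NumericVector& y_, double C_, double tol_)
      : K(K_), y(y_), C(C_), tol(tol_), eps(1e-12), n(K_.nrow()),
        alpha(n, 0.0), E(n), b(0.0) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];  // f = 0 at start
  }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    double E1 = E[i1], E2 = E[i2];
    double L, H;
    if (s > 0) {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    } else {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    }
    if (L >= H) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // degenerate direction: evaluate the objective at both clip ends
      double f1 = y1 * (E1 + b) - a1 * k11 - s * a2 * k12;
      double f2 = y2 * (E2 + b) - a2 * k22 - s * a1 * k12;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double Lobj = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double Hobj = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (Lobj < Hobj - 1e-3 * tol) a2new = L;
      else if (Lobj > Hobj + 1e-3 * tol) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }

    double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    bool free1 = a1new > eps && a1new < C - eps;
    bool free2 = a2new > eps && a2new < C - eps;
    if (free1) bnew = b1;
    else if (free2) bnew = b2;
    else bnew = 0.5 * (b1 + b2);

    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2), db = bnew - b;
    for (int i = 0; i < n; ++i)
      E[i] += d1 * K(i, i1) + d2 * K(i, i2) + db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return true;
  }

  int examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    double r2 = E2 * y2;
    if (!((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0))) return 0;
    // 1. best |E1 - E2| over non-bound points
    int best = -1;
    double gap = -1.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] > eps && alpha[i] < C - eps) {
        double g = std::fabs(E[i] - E2);
        if (g > gap) { gap = g; best = i; }
      }
    }
    if (best >= 0 && takeStep(best, i2)) return 1;
    // 2. deterministic sweep over non-bound, then all
    for (int i = 0; i < n; ++i)
      if (alpha[i] > eps && alpha[i] < C - eps && takeStep(i, i2)) return 1;
    for (int i = 0; i < n; ++i)
      if (takeStep(i, i2)) return 1;
    return 0;
  }
};

}  // namespace

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C = 1.0,
               double tol = 1e-3, int max_passes = 10000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix and labels are inconsistent");
  Smo smo(K, y, C, tol);
  int numChanged = 0;
  bool examineAll = true;
  int passes = 0;
  while ((numChanged > 0 || examineAll) && passes < max_passes) {
    numChanged = 0;
    if (examineAll) {
      for (int i = 0; i < n; ++i) numChanged += smo.examine(i);
    } else {
      for (int i = 0; i < n; ++i)
        if (smo.alpha[i] > smo.eps && smo.alpha[i] < C - smo.eps)
          numChanged += smo.examine(i);
    }
    if (examineAll) examineAll = false;
    else if (numChanged == 0) examineAll = true;
    ++passes;
  }
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(),
                                                 smo.alpha.end()),
                      _["b"] = smo.b,
                      _["passes"] = passes,
                      _["converged"] = passes < max_passes);
}
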