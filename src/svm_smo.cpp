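// Deterministic SMO solver for the C-SVC dual with a precomputed kernel.
// Small-n training inside repeated cross-validation is the target workload,
// so the implementation favours simplicity and full determinism (fixed
// iteration order, no random second-choice heuristic) over large-scale
// shrinking tricks.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Smo {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol, eps;
  std::vector<double> alpha, fcache;  // fcache[i] = sum_j a_j y_j K_ij + b
  double b;
  int n;

  Smo(const NumericMatrix& K_, const NumericVector& y_, double C_, double tol_)
      : K(K_), y(y_), C(C_), tol(tol_), eps(1e-12),
        alpha(K_.nrow(), 0.0), fcache(K_.nrow(), 0.0), b(0.0),
        n(K_.nrow()) {}

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2];
    double E1 = fcache[i1] - y1, E2 = fcache[i2] - y2;
    double s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (H - L < eps) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // degenerate kernel direction: evaluate the objective at both ends
      double f1 = y1 * E1 - a1 * k11 - s * a2 * k12;
      double f2 = y2 * E2 - a2 * k22 - s * a1 * k12;
      double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
      double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                    0.5 * L * L * k22 + s * L * L1 * k12;
      double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                    0.5 * H * H * k22 + s * H * H1 * k12;
      if (objL < objH - eps) a2new = L;
      else if (objL > objH + eps) a2new = H;
      else a2new = a2;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    if (a1new < 0) { a2new += s * a1new; a1new = 0; }
    else if (a1new > C) { a2new += s * (a1new - C); a1new = C; }
    // threshold update (Platt)
    double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + b;
    double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + b;
    double bnew;
    if (a1new > eps && a1new < C - eps) bnew = b1;
    else if (a2new > eps && a2new < C - eps) bnew = b2;
    else bnew = 0.5 * (b1 + b2);
    double db = bnew - b;
    b = bnew;
    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    for (int j = 0; j < n; ++j) {
      // fcache tracks u = sum a y K - b (Platt's convention), so the
      // threshold moves with opposite sign
      fcache[j] += d1 * K(i1, j) + d2 * K(i2, j) - db;
    }
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    return true;
  }

  bool examine(int i2) {
    double y2 = y[i2], a2 = alpha[i2];
    double E2 = fcache[i2] - y2;
    double r2 = E2 * y2;
    if ((r2 < -tol && a2 < C) || (r2 > tol && a2 > 0)) {
      // second choice: maximal |E1 - E2| over non-bound multipliers
      int best = -1;
      double bestGap = -1;
      for (int j = 0; j < n; ++j) {
        if (alpha[j] > eps && alpha[j] < C - eps) {
          double gap = std::fabs(fcache[j] - y[j] - E2);
          if (gap > bestGap) { bestGap = gap; best = j; }
        }
      }
      if (best >= 0 && takeStep(best, i2)) return true;
      for (int j = 0; j < n; ++j) {
        if (alpha[j] > eps && alpha[j] < C - eps && takeStep(j, i2)) {
          return true;
        }
      }
      for (int j = 0; j < n; ++j) {
        if (takeStep(j, i2)) return true;
      }
    }
    return false;
  }
};

}  // namespace

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C = 1.0,
               double tol = 1e-3, int max_passes = 200) {
  Smo smo(K, y, C, tol);
  int numChanged = 0;
  bool examineAll = true;
  int pass = 0;
  while ((numChanged > 0 || examineAll) && pass < max_passes) {
    ++pass;
    numChanged = 0;
    if (examineAll) {
      for (int i = 0; i < smo.n; ++i) numChanged += smo.examine(i);
    } else {
      for (int i = 0; i < smo.n; ++i) {
        if (smo.alpha[i] > smo.eps && smo.alpha[i] < C - smo.eps) {
          numChanged += smo.examine(i);
        }
      }
    }
    if (examineAll) examineAll = false;
    else if (numChanged == 0) examineAll = true;
  }
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(),
                                                 smo.alpha.end()),
                      _["b"] = -smo.b,
                      _["iterations"] = pass);
}
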