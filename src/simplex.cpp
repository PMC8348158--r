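#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex on the standard equality form
//
//   min c'x   s.t.  A x = b,  x >= 0,  b >= 0 (rows pre-normalised in R)
//
// Bland's smallest-index rule throughout, so the method cannot cycle on the
// (often highly degenerate) flux polytopes it is used on.  Problem sizes in
// this package are tiny (hundreds of rows/columns), so a full tableau is
// simpler and fast enough; no factorisation updates are attempted.
//
// Returns: status 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

static const double PIV_TOL = 1e-9;

// One simplex run on tableau T ((m+1) x (ncol+1), cost row last, RHS col
// last).  'eligible' masks columns allowed to enter (used to lock artificial
// columns out of phase 2).  Returns 0 optimal, 2 unbounded, 3 maxiter.
static int run_simplex(std::vector<double>& T, int m, int ncol,
                       std::vector<int>& basis,
                       const std::vector<bool>& eligible,
                       int max_iter) {
  const int stride = ncol + 1;            // row-major, RHS at column ncol
  for (int iter = 0; iter < max_iter; ++iter) {
    // Bland: entering column = smallest eligible index with negative reduced cost
    int enter = -1;
    for (int j = 0; j < ncol; ++j) {
      if (eligible[j] && T[(size_t)m * stride + j] < -PIV_TOL) { enter = j; break; }
    }
    if (enter < 0) return 0;              // optimal
    // Ratio test; ties broken by smallest basis variable index (Bland)
    int leave = -1;
    double best = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = T[(size_t)i * stride + enter];
      if (a > PIV_TOL) {
        double ratio = T[(size_t)i * stride + ncol] / a;
        if (leave < 0 || ratio < best - PIV_TOL ||
            (ratio < best + PIV_TOL && basis[i] < basis[leave])) {
          leave = i; best = ratio;
        }
      }
    }
    if (leave < 0) return 2;              // unbounded direction
    // Pivot on (leave, enter)
    double piv = T[(size_t)leave * stride + enter];
    for (int j = 0; j <= ncol; ++j) T[(size_t)leave * stride + j] /= piv;
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      double f = T[(size_t)i * stride + enter];
      if (std::fabs(f) > 0.0) {
        for (int j = 0; j <= ncol; ++j)
          T[(size_t)i * stride + j] -= f * T[(size_t)leave * stride + j];
        T[(size_t)i * stride + enter] = 0.0;   // kill round-off
      }
    }
    basis[leave] = enter;
  }
  return 3;
}

// [[Rcpp::export]]
List cpp_simplex(NumericMatrix A, NumericVector b, NumericVector c,
                 int max_iter = 20000) {
  const int m = A.nrow(), n = A.ncol();
  const int ncol = n + m;                 // structural + artificial
  const int stride = ncol + 1;
  std::vector<double> T((size_t)(m + 1) * stride, 0.0);
  std::vector<int> basis(m);
  std::vector<bool> eligible(ncol, true);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[(size_t)i * stride + j] = A(i, j);
    T[(size_t)i * stride + (n + i)] = 1.0;       // artificial
    T[(size_t)i * stride + ncol] = b[i];
    basis[i] = n + i;
  }
  // Phase-1 cost row: minimise sum of artificials => reduced costs are
  // -(column sums) over structural columns, RHS = -(sum b)
  for (int j = 0; j <= ncol; ++j) {
    if (j >= n && j < ncol) { T[(size_t)m * stride + j] = 0.0; continue; }
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += T[(size_t)i * stride + j];
    T[(size_t)m * stride + j] = -s;
  }

  int st = run_simplex(T, m, ncol, basis, eligible, max_iter);
  if (st == 3) return List::create(_["status"] = 3);
  double phase1 = -T[(size_t)m * stride + ncol];
  if (phase1 > 1e-7)
    return List::create(_["status"] = 1);        // infeasible

  // Drive artificials out of the basis where possible
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= n) {
      int piv_col = -1;
      for (int j = 0; j < n; ++j) {
        if (std::fabs(T[(size_t)i * stride + j]) > 1e-7) { piv_col = j; break; }
      }
      if (piv_col >= 0) {
        double piv = T[(size_t)i * stride + piv_col];
        for (int j = 0; j <= ncol; ++j) T[(size_t)i * stride + j] /= piv;
        for (int k = 0; k <= m; ++k) {
          if (k == i) continue;
          double f = T[(size_t)k * stride + piv_col];
          if (std::fabs(f) > 0.0)
            for (int j = 0; j <= ncol; ++j)
              T[(size_t)k * stride + j] -= f * T[(size_t)i * stride + j];
        }
        basis[i] = piv_col;
      }
      // else: redundant row; artificial stays basic at value ~0, harmless
    }
  }
  for (int j = n; j < ncol; ++j) eligible[j] = false;

  // Phase-2 cost row: z_j = c_j, then eliminate basic columns
  for (int j = 0; j <= ncol; ++j)
    T[(size_t)m * stride + j] = (j < n) ? c[j] : 0.0;
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    double cb = (bj < n) ? c[bj] : 0.0;
    if (cb != 0.0)
      for (int j = 0; j <= ncol; ++j)
        T[(size_t)m * stride + j] -= cb * T[(size_t)i * stride + j];
  }

  st = run_simplex(T, m, ncol, basis, eligible, max_iter);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T[(size_t)i * stride + ncol];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj);
}
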