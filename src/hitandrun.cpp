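#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate hit-and-run over the steady-state flux polytope expressed in
// null-space coordinates: feasible points are v = v0 + N u with S N = 0, so
// only the box constraints lb <= v <= ub cut the line along each null-space
// basis direction.  At every step a basis direction is drawn uniformly, the
// feasible chord through the current point is computed fresh from the current
// state (so floating-point error does not accumulate across steps), and a
// uniform point on a slightly shrunken chord is taken to stay strictly
// interior.  Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix cpp_hit_and_run(NumericMatrix N, NumericVector v0,
                              NumericVector lb, NumericVector ub,
                              int n_samples, int thinning) {
  const int n = v0.size();
  const int k = N.ncol();
  NumericMatrix out(n_samples, n);
  std::vector<double> v(v0.begin(), v0.end());
  const double dir_tol = 1e-10;
  const double shrink = 1e-9;

  RNGScope scope;
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thinning; ++t) {
      int j = (int)std::floor(unif_rand() * k);
      if (j >= k) j = k - 1;
      double tmin = -std::numeric_limits<double>::infinity();
      double tmax = std::numeric_limits<double>::infinity();
      for (int i = 0; i < n; ++i) {
        double d = N(i, j);
        if (std::fabs(d) < dir_tol) continue;
        double lo = (lb[i] - v[i]) / d;
        double hi = (ub[i] - v[i]) / d;
        if (d < 0) std::swap(lo, hi);
        if (lo > tmin) tmin = lo;
        if (hi < tmax) tmax = hi;
      }
      if (!std::isfinite(tmin) || !std::isfinite(tmax)) continue;
      double width = tmax - tmin;
      if (width <= 0) continue;               // degenerate chord, stay put
      double margin = shrink * width;
      double step = tmin + margin + unif_rand() * (width - 2.0 * margin);
      for (int i = 0; i < n; ++i) v[i] += step * N(i, j);
    }
    for (int i = 0; i < n; ++i) out(s, i) = v[i];
  }
  return out;
}
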