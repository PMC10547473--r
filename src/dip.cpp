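#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Maximal feasible prefix for a convex band fit.
//
// Given strictly increasing abscissae x with per-point bands [lo, hi],
// returns the largest k such that some convex nondecreasing function g
// satisfies lo[j] <= g(x[j]) <= hi[j] for all j < k.  Uses the fact that
// the lower convex hull of the upper bounds is the pointwise-largest
// convex function under them: the prefix is feasible iff that hull clears
// every lower bound.  The hull is grown incrementally; adding a point can
// only lower the hull over its final segment, so only that span needs
// rechecking.
static int max_prefix(const std::vector<double>& x,
                      const std::vector<double>& lo,
                      const std::vector<double>& hi) {
  const int m = (int) x.size();
  const double tol = 1e-12;
  std::vector<int> hull;
  hull.reserve(m);
  for (int j = 0; j < m; ++j) {
    if (lo[j] > hi[j] + tol) return j;  // empty band at j
    while (hull.size() >= 2) {
      int b = hull[hull.size() - 1];
      int a = hull[hull.size() - 2];
      // pop b only if it lies strictly above the chord a -> j; keeping
      // collinear vertices leaves the hull identical as a function but
      // keeps recheck spans short (linear-cost on near-uniform data)
      double lhs = (hi[b] - hi[a]) * (x[j] - x[a]);
      double rhs = (hi[j] - hi[a]) * (x[b] - x[a]);
      if (lhs <= rhs + 1e-15) break;
      hull.pop_back();
    }
    if (!hull.empty()) {
      int a = hull.back();
      double dx = x[j] - x[a];
      for (int t = a + 1; t < j; ++t) {
        double v = hi[a] + (hi[j] - hi[a]) * (x[t] - x[a]) / dx;
        if (lo[t] > v + tol) return j;  // hull dips below a lower bound
      }
    }
    hull.push_back(j);
  }
  return m;
}

// Feasibility of a unimodal CDF within a uniform band of half-width e
// around the empirical CDF of the sample summarized by distinct values v
// (increasing), counts-below cb and counts-through ct (out of n).
static bool unimodal_band_feasible(const std::vector<double>& v,
                                   const std::vector<double>& cb,
                                   const std::vector<double>& ct,
                                   int n, double e) {
  const int m = (int) v.size();
  std::vector<double> lo(m), hi(m);
  for (int j = 0; j < m; ++j) {
    lo[j] = ct[j] / n - e;
    hi[j] = cb[j] / n + e;
  }
  int pre = max_prefix(v, lo, hi);
  if (pre == m) return true;  // fully convex fit exists
  // mirror for the concave suffix: u = -x, h(u) = -g(-u) is convex
  std::vector<double> xt(m), lot(m), hit(m);
  for (int j = 0; j < m; ++j) {
    xt[j] = -v[m - 1 - j];
    lot[j] = -hi[m - 1 - j];
    hit[j] = -lo[m - 1 - j];
  }
  int suf = max_prefix(xt, lot, hit);
  // A unimodal CDF may carry an atom at its mode, so the empirical jump
  // at one candidate modal point may be absorbed by that atom: the
  // convex prefix and concave suffix together need to cover all but one
  // point.
  return pre + suf >= m - 1;
}

//' Hartigan-style dip statistic of a numeric sample
//'
//' The dip of a sample is the smallest uniform (sup-norm) band half-width
//' around its empirical CDF that admits a unimodal distribution function.
//' It is computed here directly from that definition by bisection over the
//' band half-width, testing at each width whether a convex-then-concave
//' nondecreasing function fits within the band (greatest-convex-minorant
//' feasibility on a prefix plus the mirrored check on a suffix).
//'
//' @param x numeric vector (NAs removed by the caller).
//' @return the dip statistic, a value in [0, 0.25]; 0 for degenerate
//'   (constant) samples.
//' @noRd
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  const int n = (int) xs.size();
  if (n < 2) return 0.0;
  // collapse ties to distinct values with cumulative counts
  std::vector<double> v, cb, ct;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    v.push_back(xs[i]);
    cb.push_back((double) i);
    ct.push_back((double) j);
    i = j;
  }
  if (v.size() == 1) return 0.0;
  double elo = 0.0, ehi = 0.5;
  for (int it = 0; it < 50 && (ehi - elo) > 5e-11; ++it) {
    double mid = 0.5 * (elo + ehi);
    if (unimodal_band_feasible(v, cb, ct, n, mid)) ehi = mid; else elo = mid;
  }
  return ehi;
}

//' Dip statistics of many samples stored column-wise
//' @noRd
// [[Rcpp::export(name = ".dip_stat_cols_cpp")]]
NumericVector dip_stat_cols_cpp(NumericMatrix m) {
  int B = m.ncol();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    NumericVector col = m(_, b);
    out[b] = dip_stat_cpp(col);
  }
  return out;
}
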