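#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Hartigan-style dip statistic computed from its definition: the minimal
// sup-norm distance between the empirical distribution function and the
// class of unimodal distribution functions (convex below the mode, concave
// above).  For a candidate mode at sorted point m, the best convex fit on
// [x_1, x_m] lies half-way between the points and their greatest convex
// minorant (GCM), and symmetrically the least concave majorant (LCM) on
// [x_m, x_n].  The midpoint ECDF convention F_i = (i - 1/2)/n splits the
// step ambiguity of the ECDF evenly between its left and right limits.
//
// dev[m] = max_{i <= m} ( F_i - GCM_{1..m}(x_i) ), computed incrementally
// with a monotone-chain lower hull; popped hull segments trigger a rescan
// of the affected index range, so the pass is near-linear on generic data.

static std::vector<double> prefix_gcm_dev(const std::vector<double>& x,
                                          const std::vector<double>& F) {
  const int n = (int)x.size();
  std::vector<double> dev(n, 0.0);
  std::vector<int> hull;
  hull.reserve(n);
  double cur = 0.0;
  for (int m = 0; m < n; ++m) {
    // pop hull points that are no longer on the lower convex hull
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * (F[m] - F[a]) -
                     (x[m] - x[a]) * (F[b] - F[a]);
      if (cross <= 0.0) hull.pop_back(); else break;
    }
    // ties in x: keep the lower F point only (F is increasing, so the
    // earlier point); the segment through equal x is vertical otherwise
    if (!hull.empty() && x[hull.back()] == x[m]) {
      // F[m] >= F[hull.back()]; deviation handled by rescan below
    } else {
      hull.push_back(m);
    }
    // rescan deviations over the last hull segment (covers any indices
    // whose supporting segment changed when points were popped)
    if (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double dx = x[b] - x[a];
      for (int i = a + 1; i <= m; ++i) {
        double g = (dx > 0.0) ? F[a] + (F[b] - F[a]) * (x[i] - x[a]) / dx
                              : F[a];
        double d = F[i] - g;
        if (d > cur) cur = d;
      }
    }
    dev[m] = cur;
  }
  return dev;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xr) {
  std::vector<double> x(xr.begin(), xr.end());
  std::sort(x.begin(), x.end());
  const int n = (int)x.size();
  if (n < 2) return 0.0;
  std::vector<double> F(n);
  for (int i = 0; i < n; ++i) F[i] = (i + 0.5) / n;

  // left deviations: GCM over prefixes of (x, F)
  std::vector<double> devL = prefix_gcm_dev(x, F);

  // right deviations: LCM over suffixes == GCM over prefixes of the
  // point set reflected through the origin in both axes
  std::vector<double> xr2(n), Fr2(n);
  for (int i = 0; i < n; ++i) {
    xr2[i] = -x[n - 1 - i];
    Fr2[i] = 1.0 - F[n - 1 - i];
  }
  std::vector<double> devRrev = prefix_gcm_dev(xr2, Fr2);

  double best = R_PosInf;
  for (int m = 0; m < n; ++m) {
    double dR = devRrev[n - 1 - m]; // suffix starting at m
    double d = std::max(devL[m], dR);
    if (d < best) best = d;
  }
  return 0.5 * best;
}

// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int iters, NumericVector unif) {
  // unif holds iters * n pre-drawn null samples (R-side RNG for
  // reproducibility); returns the dip of each
  NumericVector out(iters);
  for (int it = 0; it < iters; ++it) {
    NumericVector draw(unif.begin() + (R_xlen_t)it * n,
                       unif.begin() + (R_xlen_t)(it + 1) * n);
    out[it] = dip_stat_cpp(draw);
  }
  return out;
}
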