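#include <Rcpp.h>
using namespace Rcpp;

// Exact sup-norm distance from a discrete CDF to the nearest unimodal
// (convex-then-concave) fit, scanning every candidate mode point.
//
// Inputs: x strictly increasing abscissas, F the CDF evaluations at x
// (midpoint convention, ties collapsed by the R wrapper).
//
// For each prefix 1..k the maximal deviation of F above its greatest convex
// minorant (lower convex hull) is computed; for each suffix k..n the maximal
// deviation of F below its least concave majorant (upper hull). The optimal
// sup-norm unimodal fit with mode at x_k then has error
// max(pre[k], suf[k]) / 2, and the statistic is the minimum over modes.

static double prefix_hull_dev(const std::vector<double>& x,
                              const std::vector<double>& F,
                              int k, bool lower) {
  // deviation of F from the lower (or upper) convex hull of points 0..k
  std::vector<int> hull;
  hull.reserve(k + 1);
  for (int i = 0; i <= k; ++i) {
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * (F[i] - F[a]) -
                     (x[i] - x[a]) * (F[b] - F[a]);
      bool pop = lower ? (cross <= 0) : (cross >= 0);
      if (pop) hull.pop_back(); else break;
    }
    hull.push_back(i);
  }
  double dev = 0.0;
  int seg = 0;
  for (int j = 0; j <= k; ++j) {
    while (seg + 1 < (int)hull.size() - 0 && x[hull[seg + 1]] < x[j]) ++seg;
    int a = hull[seg];
    int b = (seg + 1 < (int)hull.size()) ? hull[seg + 1] : hull[seg];
    double hv;
    if (a == b || x[b] == x[a]) hv = F[a];
    else hv = F[a] + (F[b] - F[a]) * (x[j] - x[a]) / (x[b] - x[a]);
    double d = lower ? (F[j] - hv) : (hv - F[j]);
    if (d > dev) dev = d;
  }
  return dev;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs, NumericVector Fs) {
  int n = xs.size();
  if (n < 3) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::vector<double> F(Fs.begin(), Fs.end());

  std::vector<double> pre(n), suf(n);
  for (int k = 0; k < n; ++k) pre[k] = prefix_hull_dev(x, F, k, true);

  // suffix: reflect the axis so the upper hull of the suffix becomes the
  // lower-hull computation on reversed, negated data
  std::vector<double> xr(n), Fr(n);
  for (int i = 0; i < n; ++i) {
    xr[i] = -x[n - 1 - i];
    Fr[i] = -F[n - 1 - i];
  }
  for (int k = 0; k < n; ++k) {
    // prefix of reflected data of length k+1 == suffix starting at n-1-k
    suf[n - 1 - k] = prefix_hull_dev(xr, Fr, k, true);
  }

  double best = R_PosInf;
  for (int k = 0; k < n; ++k) {
    double m = std::max(pre[k], suf[k]);
    if (m < best) best = m;
  }
  return best / 2.0;
}
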