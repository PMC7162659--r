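#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Two-sample Kolmogorov-Smirnov statistic on pre-sorted inputs:
// D = sup |ECDF_x - ECDF_y| over the pooled points (tie-safe merge walk).
static double ks_sorted(const std::vector<double>& x,
                        const std::vector<double>& y) {
  const double nx = (double)x.size(), ny = (double)y.size();
  std::size_t i = 0, j = 0;
  double d = 0.0;
  while (i < x.size() && j < y.size()) {
    double v = std::min(x[i], y[j]);
    while (i < x.size() && x[i] == v) ++i;
    while (j < y.size() && y[j] == v) ++j;
    double diff = std::fabs(i / nx - j / ny);
    if (diff > d) d = diff;
  }
  // after one sample is exhausted the gap can only shrink back to 0 except
  // at the step where the remaining sample catches up; check the tail steps
  while (i < x.size()) {
    ++i;
    double diff = std::fabs(i / nx - j / ny);
    if (diff > d) d = diff;
  }
  while (j < y.size()) {
    ++j;
    double diff = std::fabs(i / nx - j / ny);
    if (diff > d) d = diff;
  }
  return d;
}

// [[Rcpp::export]]
double ks_stat_cpp(NumericVector x, NumericVector y) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());
  return ks_sorted(xs, ys);
}

// Draw m distinct indices from [0, n) via partial Fisher-Yates using R's RNG
// (so the whole Monte Carlo is reproducible through set.seed()).
static void sample_m(std::vector<int>& pool, int m, std::vector<int>& out) {
  int n = (int)pool.size();
  for (int k = 0; k < m; ++k) {
    int j = k + (int)(unif_rand() * (n - k));
    if (j >= n) j = n - 1;
    std::swap(pool[k], pool[j]);
    out[k] = pool[k];
  }
}

// Mean two-sample K-S statistic between two independent frac-subsamples of
// the RPM values >= each grid threshold, over n_iter repeats per threshold.
// rpm must be sorted ascending. Returns a matrix: col 0 = mean D, col 1 = n
// sites passing the threshold (NA mean where a subsample would have < 2
// elements).
// [[Rcpp::export]]
NumericMatrix ks_subsample_curve_cpp(NumericVector rpm_sorted,
                                     NumericVector grid,
                                     int n_iter, double frac) {
  int ng = grid.size();
  int n_all = rpm_sorted.size();
  NumericMatrix out(ng, 2);
  RNGScope scope;
  for (int g = 0; g < ng; ++g) {
    // first index with rpm >= grid[g]
    int lo = (int)(std::lower_bound(rpm_sorted.begin(), rpm_sorted.end(),
                                    grid[g]) - rpm_sorted.begin());
    int n = n_all - lo;
    int m = (int)std::ceil(frac * n);
    out(g, 1) = n;
    if (m < 2) { out(g, 0) = NA_REAL; continue; }
    std::vector<int> pool(n);
    std::vector<int> ia(m), ib(m);
    std::vector<double> xa(m), xb(m);
    double acc = 0.0;
    for (int it = 0; it < n_iter; ++it) {
      for (int k = 0; k < n; ++k) pool[k] = k;
      sample_m(pool, m, ia);
      for (int k = 0; k < n; ++k) pool[k] = k;
      sample_m(pool, m, ib);
      for (int k = 0; k < m; ++k) {
        xa[k] = rpm_sorted[lo + ia[k]];
        xb[k] = rpm_sorted[lo + ib[k]];
      }
      std::sort(xa.begin(), xa.end());
      std::sort(xb.begin(), xb.end());
      acc += ks_sorted(xa, xb);
    }
    out(g, 0) = acc / n_iter;
  }
  return out;
}
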