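#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Quantile with linear interpolation between order statistics (R type 7)
// on an already-sorted vector.
static double q_type7(const std::vector<double>& s, double p) {
  const int n = (int)s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = lo + 1;
  if (hi >= n) return s[n - 1];
  return s[lo] + (h - lo) * (s[hi] - s[lo]);
}

// Trailing-window summary features for one channel.
// Columns: mean, sd, min, max, median, iqr, slope, frac_missing.
// Window for row i covers indices [i - w + 1, i]; NA values are excluded
// from every statistic except frac_missing. Rows whose window holds no
// observation get NA in every column and frac_missing = 1.
// [[Rcpp::export(name = ".roll_view_features")]]
NumericMatrix roll_view_features(NumericVector x, int w) {
  const int n = x.size();
  NumericMatrix out(n, 8);
  std::vector<double> buf;
  buf.reserve(w);
  std::vector<double> xs, ts;
  xs.reserve(w);
  ts.reserve(w);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - w + 1);
    int span = i - lo + 1;
    xs.clear();
    ts.clear();
    for (int j = lo; j <= i; ++j) {
      if (!NumericVector::is_na(x[j])) {
        xs.push_back(x[j]);
        ts.push_back((double)(j - lo));
      }
    }
    int m = (int)xs.size();
    double fm = 1.0 - (double)m / (double)span;
    if (m == 0) {
      for (int c = 0; c < 7; ++c) out(i, c) = NA_REAL;
      out(i, 7) = 1.0;
      continue;
    }
    double sum = 0.0, mn = xs[0], mx = xs[0];
    for (double v : xs) {
      sum += v;
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    double mean = sum / m;
    double sdv = 0.0;
    if (m > 1) {
      double ss = 0.0;
      for (double v : xs) ss += (v - mean) * (v - mean);
      sdv = std::sqrt(ss / (m - 1));
    }
    buf = xs;
    std::sort(buf.begin(), buf.end());
    double med = q_type7(buf, 0.5);
    double iqr = q_type7(buf, 0.75) - q_type7(buf, 0.25);
    // OLS slope of value against within-window minute index
    double slope = 0.0;
    if (m > 1) {
      double tbar = 0.0;
      for (double t : ts) tbar += t;
      tbar /= m;
      double sxy = 0.0, sxx = 0.0;
      for (int j = 0; j < m; ++j) {
        sxy += (ts[j] - tbar) * (xs[j] - mean);
        sxx += (ts[j] - tbar) * (ts[j] - tbar);
      }
      if (sxx > 0) slope = sxy / sxx;
    }
    out(i, 0) = mean;
    out(i, 1) = sdv;
    out(i, 2) = mn;
    out(i, 3) = mx;
    out(i, 4) = med;
    out(i, 5) = iqr;
    out(i, 6) = slope;
    out(i, 7) = fm;
  }
  colnames(out) = CharacterVector::create("mean", "sd", "min", "max",
                                          "median", "iqr", "slope",
                                          "frac_missing");
  return out;
}
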