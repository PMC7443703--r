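#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Median of a sorted vector.
static double sorted_median(const std::vector<double>& s) {
  size_t n = s.size();
  if (n % 2 == 1) return s[n / 2];
  return 0.5 * (s[n / 2 - 1] + s[n / 2]);
}

// k-th smallest (0-based) absolute deviation |s[i] - m| for sorted s.
// The deviations form two sorted runs (below and above m), merged with
// two pointers in O(n).
static double kth_abs_dev(const std::vector<double>& s, double m, size_t k) {
  // position of first element >= m
  size_t split = std::lower_bound(s.begin(), s.end(), m) - s.begin();
  // left run: s[split-1] down to s[0] has increasing deviation
  // right run: s[split] up to s[n-1] has increasing deviation
  size_t li = split, ri = split;  // li counts used left elements
  size_t taken = 0;
  double last = 0.0;
  size_t n = s.size();
  while (taken <= k) {
    bool has_left = li > 0;
    bool has_right = ri < n;
    double dl = has_left ? (m - s[li - 1]) : 0.0;
    double dr = has_right ? (s[ri] - m) : 0.0;
    if (has_left && (!has_right || dl <= dr)) {
      last = dl;
      --li;
    } else if (has_right) {
      last = dr;
      ++ri;
    } else {
      break;
    }
    ++taken;
  }
  return last;
}

// Median absolute deviation about m over sorted s, in O(n).
static double sorted_mad(const std::vector<double>& s, double m) {
  size_t n = s.size();
  if (n % 2 == 1) return kth_abs_dev(s, m, n / 2);
  double a = kth_abs_dev(s, m, n / 2 - 1);
  double b = kth_abs_dev(s, m, n / 2);
  return 0.5 * (a + b);
}

// Sliding-window Hampel identifier over a spectrum part.
//
// x: one-sided spectrum part (real or imaginary coefficients).
// half: window half-width in bins; the window at bin i covers
//       [i-half, i+half] intersected with the evaluated range padded to
//       the full axis (truncated at the spectrum edges).
// C: threshold in robust-SD units.
// eval: logical mask of bins on which the identifier runs (bins outside
//       are never modified but still contribute to windows).
// use_mad: robust scale = 1.4826 * MAD if true, window SD if false.
//
// Medians and scales are computed from the *input* spectrum (detection is
// not sequential), outliers are replaced by the window median.
// [[Rcpp::export]]
NumericVector hampel_identify_cpp(NumericVector x, int half, double C,
                                  LogicalVector eval, bool use_mad) {
  int n = x.size();
  NumericVector out = clone(x);
  std::vector<double> win;
  win.reserve(2 * half + 2);
  int lo = -1, hi = -2;  // current window [lo, hi], empty

  // running sums for the SD variant
  double sum = 0.0, sumsq = 0.0;

  auto add = [&](int j) {
    double v = x[j];
    win.insert(std::upper_bound(win.begin(), win.end(), v), v);
    sum += v;
    sumsq += v * v;
  };
  auto drop = [&](int j) {
    double v = x[j];
    win.erase(std::lower_bound(win.begin(), win.end(), v));
    sum -= v;
    sumsq -= v * v;
  };

  for (int i = 0; i < n; ++i) {
    if (!eval[i]) continue;
    int nlo = std::max(0, i - half);
    int nhi = std::min(n - 1, i + half);
    if (nlo > hi || hi < lo) {  // disjoint from current window: rebuild
      win.clear();
      sum = sumsq = 0.0;
      for (int j = nlo; j <= nhi; ++j) add(j);
    } else {
      for (int j = lo; j < nlo; ++j) drop(j);
      for (int j = hi + 1; j <= nhi; ++j) add(j);
    }
    lo = nlo;
    hi = nhi;
    double m = sorted_median(win);
    double scale;
    if (use_mad) {
      scale = 1.4826 * sorted_mad(win, m);
    } else {
      int w = static_cast<int>(win.size());
      double var = (sumsq - sum * sum / w) / std::max(1, w - 1);
      scale = std::sqrt(std::max(0.0, var));
    }
    if (std::fabs(x[i] - m) > C * scale) out[i] = m;
  }
  return out;
}
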