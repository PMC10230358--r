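#include <Rcpp.h>
#include <set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Median of a scratch buffer (average of the two middle order statistics for
// even counts, matching stats::median).
static double buf_median(std::vector<double> &buf) {
  const size_t n = buf.size();
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return (lo + hi) / 2.0;
}

// Causal rolling median: out[t] = median of non-missing x[s], s in
// [t - window, t - 1] (clipped at the start of the series); NA when fewer
// than min_obs values are present in the window.
// [[Rcpp::export]]
NumericVector roll_median_prev(NumericVector x, int window, int min_obs) {
  const int n = x.size();
  NumericVector out(n, NA_REAL);
  if (window < 1) stop("window must be >= 1");
  if (min_obs < 1) min_obs = 1;
  std::vector<double> buf;
  buf.reserve(window);
  for (int t = 0; t < n; ++t) {
    int lo = t - window;
    if (lo < 0) lo = 0;
    buf.clear();
    for (int s = lo; s < t; ++s)
      if (!NumericVector::is_na(x[s])) buf.push_back(x[s]);
    if ((int)buf.size() >= min_obs) out[t] = buf_median(buf);
  }
  return out;
}

// Streaming expanding median via two balanced multisets (max-side `low`,
// min-side `high`): out[t] = median of all non-missing x[s] with s < t,
// NA until at least one value has been seen.
// [[Rcpp::export]]
NumericVector expanding_median_prev(NumericVector x) {
  const int n = x.size();
  NumericVector out(n, NA_REAL);
  std::multiset<double> low, high; // invariant: |low| == |high| or |low| == |high| + 1
  for (int t = 0; t < n; ++t) {
    size_t nl = low.size(), nh = high.size();
    if (nl + nh > 0) {
      out[t] = (nl > nh) ? *low.rbegin()
                         : (*low.rbegin() + *high.begin()) / 2.0;
    }
    if (!NumericVector::is_na(x[t])) {
      double v = x[t];
      if (low.empty() || v <= *low.rbegin()) low.insert(v); else high.insert(v);
      if (low.size() > high.size() + 1) {
        high.insert(*low.rbegin());
        low.erase(std::prev(low.end()));
      } else if (high.size() > low.size()) {
        low.insert(*high.begin());
        high.erase(high.begin());
      }
    }
  }
  return out;
}
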