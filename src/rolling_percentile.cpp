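#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window percentile with linear interpolation between order
// statistics (quantile type 7). The window at frame t is
// [t - half_window, t + half_window] intersected with the trace, i.e.
// truncated (not reflected) at the edges. A sorted buffer is maintained
// incrementally: one insertion and one removal per step, so the cost is
// O(n * log w + n * w) memmove-bound rather than O(n * w log w).

// [[Rcpp::export]]
NumericVector rolling_percentile_cpp(NumericVector x, int half_window,
                                     double pct) {
  const int n = x.size();
  if (n == 0) return NumericVector(0);
  if (half_window < 0) stop("half_window must be >= 0");
  if (pct < 0.0 || pct > 100.0) stop("pct must lie in [0, 100]");
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("non-finite value in trace");

  NumericVector out(n);
  std::vector<double> win;
  win.reserve(2 * half_window + 2);

  // initial window for t = 0: [0, min(half_window, n-1)]
  int hi = std::min(half_window, n - 1);
  for (int i = 0; i <= hi; ++i) win.push_back(x[i]);
  std::sort(win.begin(), win.end());

  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      int add = t + half_window;        // new right edge
      if (add <= n - 1) {
        std::vector<double>::iterator it =
            std::upper_bound(win.begin(), win.end(), x[add]);
        win.insert(it, x[add]);
      }
      int drop = t - 1 - half_window;   // old left edge
      if (drop >= 0) {
        std::vector<double>::iterator it =
            std::lower_bound(win.begin(), win.end(), x[drop]);
        win.erase(it);
      }
    }
    const int w = (int)win.size();
    double h = (w - 1) * pct / 100.0;
    int lo = (int)std::floor(h);
    double frac = h - lo;
    double q = win[lo];
    if (frac > 0.0 && lo + 1 < w) q += frac * (win[lo + 1] - win[lo]);
    out[t] = q;
  }
  return out;
}
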