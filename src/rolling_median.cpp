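#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact median of buf[0..len-1] (buf is scratch, reordered in place).
// Even counts take the arithmetic mean of the two middle order statistics.
static double window_median(std::vector<double>& buf, int len) {
  int m = len / 2;
  std::nth_element(buf.begin(), buf.begin() + m, buf.begin() + len);
  double hi = buf[m];
  if (len % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + m);
  return 0.5 * (lo + hi);
}

// Centered rolling median with truncated (shrinking) windows at both edges.
// For position i (0-based) the window covers [i - (N-1)/2, i + N/2]
// clamped to the signal, so interior windows hold exactly N samples.
// [[Rcpp::export]]
NumericVector rolling_median_cpp(NumericVector x, int N) {
  if (N < 1) stop("N must be >= 1");
  int n = x.size();
  NumericVector out(n);
  int off_lo = (N - 1) / 2, off_hi = N / 2;
  std::vector<double> buf(N);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - off_lo);
    int hi = std::min(n - 1, i + off_hi);
    int len = hi - lo + 1;
    std::copy(x.begin() + lo, x.begin() + hi + 1, buf.begin());
    out[i] = window_median(buf, len);
  }
  return out;
}

// Row-wise rolling median for a matrix of windows (one window per row).
// [[Rcpp::export]]
NumericMatrix rolling_median_rows_cpp(NumericMatrix w, int N) {
  if (N < 1) stop("N must be >= 1");
  int nr = w.nrow(), nc = w.ncol();
  NumericMatrix out(nr, nc);
  int off_lo = (N - 1) / 2, off_hi = N / 2;
  std::vector<double> row(nc), buf(N);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) row[c] = w(r, c);
    for (int i = 0; i < nc; ++i) {
      int lo = std::max(0, i - off_lo);
      int hi = std::min(nc - 1, i + off_hi);
      int len = hi - lo + 1;
      std::copy(row.begin() + lo, row.begin() + hi + 1, buf.begin());
      out(r, i) = window_median(buf, len);
    }
  }
  return out;
}
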