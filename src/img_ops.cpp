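#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// reflect index into [0, n)
static inline int refl(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// k x k running median with reflected borders (k odd)
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(k * k);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      buf.clear();
      for (int dr = -h; dr <= h; ++dr)
        for (int dc = -h; dc <= h; ++dc)
          buf.push_back(img(refl(r + dr, nr), refl(c + dc, nc)));
      size_t m = buf.size() / 2;  // k*k odd
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(r, c) = buf[m];
    }
  }
  return out;
}

// strict local maxima within a disk of `radius` pixels, among pixels with
// value above `threshold`; returns 0-based (row, col) pairs
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericMatrix img, double radius,
                               double threshold) {
  int nr = img.nrow(), nc = img.ncol(), h = (int)std::ceil(radius);
  double r2 = radius * radius;
  std::vector<int> rows, cols;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double v = img(r, c);
      if (v <= threshold) continue;
      bool is_max = true;
      for (int dr = -h; dr <= h && is_max; ++dr) {
        for (int dc = -h; dc <= h; ++dc) {
          if (dr == 0 && dc == 0) continue;
          if (dr * dr + dc * dc > r2) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double u = img(rr, cc);
          // strictness with deterministic tie-break: on a plateau keep the
          // lexicographically smallest (row, col)
          if (u > v || (u == v && (rr < r || (rr == r && cc < c)))) {
            is_max = false;
            break;
          }
        }
      }
      if (is_max) {
        rows.push_back(r);
        cols.push_back(c);
      }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}
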