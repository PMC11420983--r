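#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Count pairs (i < j) with y[i] > y[j] by merge sort (Knight's algorithm).
static long long merge_count(std::vector<double>& y, std::vector<double>& buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  long long cnt = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {            // strict: equal values are not discordant
      cnt += (long long)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return cnt;
}

static long long tie_pairs(const std::vector<double>& v) {
  long long t = 0, run = 1;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) ++run;
    else { t += run * (run - 1) / 2; run = 1; }
  }
  t += run * (run - 1) / 2;
  return t;
}

// Kendall tau-b with tie correction in O(n log n).
// [[Rcpp::export(name = ".kendall_tau_b")]]
double kendall_tau_b(NumericVector x, NumericVector y) {
  const size_t n = x.size();
  if (y.size() != (R_xlen_t)n) stop("x and y must have equal length");
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> xs(n), ys(n);
  for (size_t i = 0; i < n; ++i) { xs[i] = x[ord[i]]; ys[i] = y[ord[i]]; }

  long long n0 = (long long)n * (n - 1) / 2;
  long long n1 = tie_pairs(xs);
  // joint ties: runs of equal (x, y)
  long long n3 = 0, run = 1;
  for (size_t i = 1; i < n; ++i) {
    if (xs[i] == xs[i - 1] && ys[i] == ys[i - 1]) ++run;
    else { n3 += run * (run - 1) / 2; run = 1; }
  }
  n3 += run * (run - 1) / 2;

  std::vector<double> buf(n);
  long long dis = merge_count(ys, buf, 0, n);  // ys now sorted
  long long n2 = tie_pairs(ys);

  double den = std::sqrt((double)(n0 - n1)) * std::sqrt((double)(n0 - n2));
  if (den == 0.0) return NA_REAL;
  double s = (double)(n0 - n1 - n2 + n3) - 2.0 * (double)dis;
  return s / den;
}
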