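#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact voxel traversal of a polyline given in *shifted* continuous voxel
// coordinates (cell i spans [i, i+1)). For every segment the parametric
// crossings of integer planes are located, and the cell of each interval
// midpoint is recorded. Returns the visited cells (0-based triplets) in
// traversal order with consecutive duplicates removed; out-of-grid cells
// are kept here and clipped by the R wrapper.
// [[Rcpp::export(name = ".traverse_cells")]]
IntegerMatrix traverse_cells(NumericMatrix s) {
  const int n = s.nrow();
  std::vector<int> out;
  out.reserve(64);
  int last[3] = {INT_MIN, INT_MIN, INT_MIN};
  std::vector<double> ts;
  for (int seg = 0; seg + 1 < n; ++seg) {
    double p0[3], d[3];
    bool zero = true;
    for (int a = 0; a < 3; ++a) {
      p0[a] = s(seg, a);
      d[a] = s(seg + 1, a) - p0[a];
      if (d[a] != 0.0) zero = false;
    }
    if (zero) continue;  // degenerate segment; wrapper warns
    ts.clear();
    ts.push_back(0.0);
    ts.push_back(1.0);
    for (int a = 0; a < 3; ++a) {
      if (d[a] == 0.0) continue;
      double lo = std::min(p0[a], p0[a] + d[a]);
      double hi = std::max(p0[a], p0[a] + d[a]);
      for (double m = std::ceil(lo); m <= std::floor(hi); m += 1.0) {
        if (m > lo && m < hi) ts.push_back((m - p0[a]) / d[a]);
      }
    }
    std::sort(ts.begin(), ts.end());
    for (size_t t = 0; t + 1 < ts.size(); ++t) {
      double mid = 0.5 * (ts[t] + ts[t + 1]);
      int c[3];
      for (int a = 0; a < 3; ++a)
        c[a] = (int)std::floor(p0[a] + mid * d[a]);
      if (c[0] != last[0] || c[1] != last[1] || c[2] != last[2]) {
        out.push_back(c[0]); out.push_back(c[1]); out.push_back(c[2]);
        last[0] = c[0]; last[1] = c[1]; last[2] = c[2];
      }
    }
    // cell of the far endpoint (half-open convention)
    int c[3];
    for (int a = 0; a < 3; ++a)
      c[a] = (int)std::floor(s(seg + 1, a));
    if (c[0] != last[0] || c[1] != last[1] || c[2] != last[2]) {
      out.push_back(c[0]); out.push_back(c[1]); out.push_back(c[2]);
      last[0] = c[0]; last[1] = c[1]; last[2] = c[2];
    }
  }
  const int m = (int)(out.size() / 3);
  IntegerMatrix res(m, 3);
  for (int i = 0; i < m; ++i) {
    res(i, 0) = out[3 * i];
    res(i, 1) = out[3 * i + 1];
    res(i, 2) = out[3 * i + 2];
  }
  return res;
}
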