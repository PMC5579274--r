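#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Equal-frequency binning with tie handling: edges are type-7 quantiles at
// k/nbin; bin = 1 + number of edges strictly below the value.
static std::vector<int> equibin(const std::vector<double>& v, int nbin) {
  const int n = (int)v.size();
  std::vector<double> s(v);
  std::sort(s.begin(), s.end());
  std::vector<double> edges;
  for (int k = 1; k < nbin; ++k) {
    const double h = (n - 1) * (double)k / nbin;
    const int j = (int)std::floor(h);
    const double g = h - j;
    edges.push_back((1.0 - g) * s[j] + g * s[std::min(j + 1, n - 1)]);
  }
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) {
    int bi = 0;
    for (size_t k = 0; k < edges.size(); ++k)
      if (v[i] > edges[k]) ++bi;
    b[i] = bi;  // 0-based bin
  }
  return b;
}

// Maximal mutual information (bits) between a fixed `rows`-level
// equipartition of `ry` and an optimized column partition of `cx` into at
// most `cols` parts, with candidate boundaries restricted to `K` superclump
// edges (the MINE heuristic). Dynamic programming over superclump prefixes:
// I = H(row) - H(row|col) and -H(row|col) is additive over columns.
static double optimized_mi(const std::vector<double>& cx,
                           const std::vector<double>& ry_vals,
                           int rows, int cols, int clump_factor) {
  const int n = (int)cx.size();
  std::vector<int> rbin = equibin(ry_vals, rows);
  const int K = std::min(n, clump_factor * cols);
  std::vector<int> cbin = equibin(cx, K);

  // counts per superclump x row (some clumps may be empty under ties)
  std::vector<std::vector<double> > cum(K + 1, std::vector<double>(rows, 0.0));
  for (int i = 0; i < n; ++i) cum[cbin[i] + 1][std::min(rbin[i], rows - 1)] += 1.0;
  for (int k = 1; k <= K; ++k)
    for (int r = 0; r < rows; ++r) cum[k][r] += cum[k - 1][r];

  // column contribution of clumps (a, b]: sum_r (c_r/n) log2(c_r / tot)
  std::vector<std::vector<double> > val(K + 1, std::vector<double>(K + 1, 0.0));
  for (int a = 0; a <= K; ++a)
    for (int b = a + 1; b <= K; ++b) {
      double tot = 0.0;
      for (int r = 0; r < rows; ++r) tot += cum[b][r] - cum[a][r];
      double acc = 0.0;
      if (tot > 0)
        for (int r = 0; r < rows; ++r) {
          const double c = cum[b][r] - cum[a][r];
          if (c > 0) acc += (c / n) * std::log2(c / tot);
        }
      val[a][b] = acc;
    }

  const double NEG = -1e18;
  std::vector<std::vector<double> > f(K + 1, std::vector<double>(cols + 1, NEG));
  f[0][0] = 0.0;
  for (int m = 1; m <= cols; ++m)
    for (int k = 1; k <= K; ++k)
      for (int t = m - 1; t < k; ++t)
        if (f[t][m - 1] > NEG / 2)
          f[k][m] = std::max(f[k][m], f[t][m - 1] + val[t][k]);
  double best = NEG;
  for (int m = 1; m <= cols; ++m) best = std::max(best, f[K][m]);

  double hrow = 0.0;
  for (int r = 0; r < rows; ++r) {
    const double c = cum[K][r];
    if (c > 0) hrow -= (c / n) * std::log2(c / n);
  }
  return hrow + best;
}

// [[Rcpp::export]]
double cpp_mic(NumericVector x, NumericVector y, double alpha, int clump_factor) {
  const int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  const int B = std::max(4, (int)std::floor(std::pow((double)n, alpha)));
  double best = 0.0;
  for (int i = 2; i * 2 <= B; ++i)
    for (int j = 2; i * j <= B; ++j) {
      const double denom = std::log2((double)std::min(i, j));
      double mi = optimized_mi(vx, vy, i, j, clump_factor);
      if (mi / denom > best) best = mi / denom;
      mi = optimized_mi(vy, vx, i, j, clump_factor);
      if (mi / denom > best) best = mi / denom;
    }
  return std::min(1.0, best);
}
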