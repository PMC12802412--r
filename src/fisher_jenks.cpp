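#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Fisher-Jenks optimal 1-D classification: dynamic program minimizing the
// within-class sum of squared deviations over contiguous classes of the
// sorted values. O(k n^2) time, O(k n) space. Input must be sorted
// ascending. Returns the 0-based index of the first element of each class
// (length k, first entry 0) plus the optimal SSW.

// cost(i, j): SSW of x[i..j] inclusive, from prefix sums in O(1).
static inline double segCost(const std::vector<double>& cs,
                             const std::vector<double>& cs2,
                             int i, int j) {
  double s  = cs[j + 1] - cs[i];
  double s2 = cs2[j + 1] - cs2[i];
  int n = j - i + 1;
  return s2 - s * s / n;
}

// [[Rcpp::export(name = ".fisherJenksCpp")]]
List fisherJenksCpp(NumericVector xs, int k) {
  int n = xs.size();
  if (k < 1 || k > n) stop("k must be in 1..n");
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1]  = cs[i] + xs[i];
    cs2[i + 1] = cs2[i] + xs[i] * xs[i];
  }
  const double INF = std::numeric_limits<double>::infinity();
  // dp[c][j]: min SSW of x[0..j] split into c+1 classes
  std::vector<std::vector<double>> dp(k, std::vector<double>(n, INF));
  std::vector<std::vector<int>> back(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) dp[0][j] = segCost(cs, cs2, 0, j);
  for (int c = 1; c < k; ++c) {
    for (int j = c; j < n; ++j) {
      double best = INF; int bi = c;
      for (int i = c; i <= j; ++i) {
        double v = dp[c - 1][i - 1] + segCost(cs, cs2, i, j);
        if (v < best - 1e-15) { best = v; bi = i; }
      }
      dp[c][j] = best;
      back[c][j] = bi;
    }
  }
  IntegerVector starts(k);
  int j = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    int i = back[c][j];
    starts[c] = i;
    j = i - 1;
  }
  starts[0] = 0;
  return List::create(_["starts"] = starts, _["ssw"] = dp[k - 1][n - 1]);
}
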