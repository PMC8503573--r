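// Exact Fisher-Jenks natural breaks: dynamic programme minimizing the total
// within-class sum of squared deviations over contiguous partitions of the
// sorted values. O(k n^2). Tied optima are resolved deterministically: the
// latest minimizing cut wins at every stage.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_jenks(NumericVector sorted, int k) {
  const int n = sorted.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + sorted[i];
    cs2[i + 1] = cs2[i] + sorted[i] * sorted[i];
  }
  // ssd of values i..j inclusive (0-based)
  auto ssd = [&](int i, int j) {
    double s = cs[j + 1] - cs[i], s2 = cs2[j + 1] - cs2[i];
    int m = j - i + 1;
    return s2 - s * s / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  // D[c][j]: best cost of first j+1 values in c+1 classes; B backtracks the
  // start index of the last class.
  std::vector<std::vector<double> > D(k, std::vector<double>(n, INF));
  std::vector<std::vector<int> > B(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) D[0][j] = ssd(0, j);
  for (int c = 1; c < k; ++c) {
    for (int j = c; j < n; ++j) {
      double best = INF; int bi = c;
      for (int i = c; i <= j; ++i) {
        double cost = D[c - 1][i - 1] + ssd(i, j);
        if (cost <= best) { best = cost; bi = i; }
      }
      D[c][j] = best;
      B[c][j] = bi;
    }
  }
  // recover class boundaries: last index of each of the first k-1 classes
  IntegerVector lastIdx(k - 1);
  int j = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    int i = B[c][j];
    lastIdx[c - 1] = i;  // 0-based index of first value of class c
    j = i - 1;
  }
  NumericVector breaks(k - 1);
  for (int c = 0; c < k - 1; ++c) breaks[c] = sorted[lastIdx[c] - 1];
  return List::create(_["breaks"] = breaks, _["ssd"] = D[k - 1][n - 1]);
}
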