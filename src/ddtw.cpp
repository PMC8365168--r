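#include <Rcpp.h>
using namespace Rcpp;

// Accumulated-cost dynamic programming for DTW on derivative sequences.
// Local cost is the squared difference; steps are diagonal, vertical,
// horizontal. Returns c(total cost of the optimal path, its length in
// cells). Ties between predecessors prefer diagonal, then vertical
// (i-1, j), then horizontal (i, j-1) — the R-level brute-force oracle in
// the test suite uses the same ordering.
// [[Rcpp::export]]
NumericVector dtw_core(NumericVector da, NumericVector db) {
  const int n = da.size(), m = db.size();
  NumericMatrix C(n, m);
  IntegerMatrix L(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = da[i] - db[j];
      double cost = d * d;
      if (i == 0 && j == 0) {
        C(i, j) = cost; L(i, j) = 1;
      } else if (i == 0) {
        C(i, j) = C(i, j - 1) + cost; L(i, j) = L(i, j - 1) + 1;
      } else if (j == 0) {
        C(i, j) = C(i - 1, j) + cost; L(i, j) = L(i - 1, j) + 1;
      } else {
        double best = C(i - 1, j - 1); int len = L(i - 1, j - 1);
        if (C(i - 1, j) < best) { best = C(i - 1, j); len = L(i - 1, j); }
        if (C(i, j - 1) < best) { best = C(i, j - 1); len = L(i, j - 1); }
        C(i, j) = best + cost; L(i, j) = len + 1;
      }
    }
  }
  return NumericVector::create(C(n - 1, m - 1), (double)L(n - 1, m - 1));
}
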