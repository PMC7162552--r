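#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Null distribution of the ECDF sup-difference under resampling of x query
// genes without replacement from the background. grid_idx maps each
// background gene to its 1-based position on the sorted unique signal grid;
// b_cdf is the background cumulative on that grid. Uses R's RNG so results
// are reproducible with set.seed().
// [[Rcpp::export]]
NumericVector cpp_perm_dsup(IntegerVector grid_idx, NumericVector b_cdf,
                            int x, int n_perm) {
  const int n = grid_idx.size();
  const int g = b_cdf.size();
  if (x < 1 || x > n) stop("query size out of range");
  NumericVector out(n_perm);
  std::vector<int> pool(grid_idx.begin(), grid_idx.end());
  std::vector<int> counts(g);
  for (int r = 0; r < n_perm; ++r) {
    // partial Fisher-Yates: first x entries become the resampled query
    for (int i = 0; i < x; ++i) {
      int j = i + static_cast<int>(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
    }
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < x; ++i) ++counts[pool[i] - 1];
    double acc = 0.0, best = 0.0;
    for (int k = 0; k < g; ++k) {
      acc += counts[k];
      double diff = b_cdf[k] - acc / x;
      if (diff > best) best = diff;
    }
    out[r] = best;
  }
  return out;
}
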