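// Pairwise shared-tract accumulation for the nSL statistic.
//
// For every unordered pair of haplotypes and every site where the pair is
// identical, the shared tract is the maximal run of consecutive segregating
// sites containing the focal site over which the pair matches, truncated at
// the matrix edges and capped at `cap` sites on each side of the focal site.
// Tract lengths are accumulated per site into the derived-class sum (both
// haplotypes carry 1) or the ancestral-class sum (both carry 0). Dividing by
// choose(class size, 2) in R gives SL_D and SL_A.

#include <Rcpp.h>
using namespace Rcpp;

// X is sites x haplotypes (column-major => one haplotype contiguous)
// [[Rcpp::export]]
List nsl_pairwise_cpp(IntegerMatrix X, int cap) {
  const int S = X.nrow();
  const int n = X.ncol();
  NumericVector sum_a(S), sum_d(S);
  if (S == 0 || n < 2) return List::create(_["sum_a"] = sum_a, _["sum_d"] = sum_d);

  const int* xp = INTEGER(X);
  for (int i = 0; i < n; ++i) {
    const int* hi = xp + (size_t) i * S;
    for (int j = i + 1; j < n; ++j) {
      const int* hj = xp + (size_t) j * S;
      int a = 0;                       // start of current matching block
      for (int s = 0; s <= S; ++s) {
        bool mismatch = (s == S) || (hi[s] != hj[s]);
        if (!mismatch) continue;
        int b = s - 1;                 // block is [a, b]
        for (int t = a; t <= b; ++t) {
          int left = t - a; if (left > cap) left = cap;
          int right = b - t; if (right > cap) right = cap;
          double len = 1.0 + left + right;
          if (hi[t]) sum_d[t] += len; else sum_a[t] += len;
        }
        a = s + 1;
      }
    }
  }
  return List::create(_["sum_a"] = sum_a, _["sum_d"] = sum_d);
}
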