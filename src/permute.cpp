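#include <Rcpp.h>
using namespace Rcpp;

// Permute each column independently (Fisher-Yates with R's RNG, so results
// are reproducible under set.seed). NA entries permute along with the rest.
// [[Rcpp::export]]
NumericMatrix permute_columns(const NumericMatrix& X) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(clone(X));
  RNGScope scope;
  for (int j = 0; j < m; ++j) {
    double* col = &out(0, j);
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(col[i], col[k]);
    }
  }
  return out;
}
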