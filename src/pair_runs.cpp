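#include <Rcpp.h>
using namespace Rcpp;

// Identity-by-state run lengths for all unordered haplotype pairs.
//
// H: complete 0/1 haplotype matrix (rows = haplotypes). cols: 1-based column
// indices ordered outward from the window midpoint. For each pair (i < j, in
// the order (1,2), (1,3), ..., (2,3), ...) returns the number of leading
// columns over which the two haplotypes are identical.
// [[Rcpp::export]]
IntegerVector pair_run_lengths(const IntegerMatrix& H, const IntegerVector& cols) {
  const int nh = H.nrow();
  const int nc = cols.size();
  const R_xlen_t np = (R_xlen_t)nh * (nh - 1) / 2;
  IntegerVector out(no_init(np));
  std::vector<const int*> colptr(nc);
  for (int t = 0; t < nc; ++t) colptr[t] = &H(0, cols[t] - 1);
  R_xlen_t k = 0;
  for (int i = 0; i < nh - 1; ++i) {
    for (int j = i + 1; j < nh; ++j, ++k) {
      int t = 0;
      while (t < nc && colptr[t][i] == colptr[t][j]) ++t;
      out[k] = t;
    }
  }
  return out;
}
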