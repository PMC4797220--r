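#include <Rcpp.h>
using namespace Rcpp;

// Locus-IBD matrix assembly. For every unordered haplotype pair the
// identity-by-state run lengths L, R away from the window midpoint are
// computed (columns ordered outward on each side), then the two-hypothesis
// posterior p = phi s / (phi s + (1 - phi) c) with survival
// s = exp(-2 T d) and chance-IBS c = prod of population homozygosities over
// the run markers. dme_left[t] / dme_right[t] give the genetic distance from
// the midpoint to the t-th marker of the side; cuml / cumr are cumulative
// log-homozygosities with a leading 0.
// [[Rcpp::export]]
NumericMatrix locibd_fill(const IntegerMatrix& H, const IntegerVector& leftcols,
                          const IntegerVector& rightcols,
                          const NumericVector& dme_left,
                          const NumericVector& dme_right,
                          const NumericVector& cuml, const NumericVector& cumr,
                          double T, double phi) {
  const int nh = H.nrow();
  const int ncl = leftcols.size(), ncr = rightcols.size();
  std::vector<const int*> lp(ncl), rp(ncr);
  for (int t = 0; t < ncl; ++t) lp[t] = &H(0, leftcols[t] - 1);
  for (int t = 0; t < ncr; ++t) rp[t] = &H(0, rightcols[t] - 1);
  // p depends on the pair only through (L, R): tabulate once per window
  std::vector<double> ptab((ncl + 1) * (ncr + 1));
  for (int L = 0; L <= ncl; ++L) {
    for (int R = 0; R <= ncr; ++R) {
      double d = (L > 0 ? dme_left[L - 1] : 0.0) + (R > 0 ? dme_right[R - 1] : 0.0);
      double s = std::exp(-2.0 * T * d);
      double c = std::exp(cuml[L] + cumr[R]);
      ptab[L * (ncr + 1) + R] = phi * s / (phi * s + (1.0 - phi) * c);
    }
  }
  NumericMatrix M(nh, nh);
  // fill the lower triangle column-wise (contiguous writes), mirror after
  for (int i = 0; i < nh - 1; ++i) {
    double* Mi = &M(0, i);
    for (int j = i + 1; j < nh; ++j) {
      int L = 0, R = 0;
      while (L < ncl && lp[L][i] == lp[L][j]) ++L;
      while (R < ncr && rp[R][i] == rp[R][j]) ++R;
      Mi[j] = ptab[L * (ncr + 1) + R];
    }
  }
  for (int i = 0; i < nh; ++i) {
    M(i, i) = 1.0;
    for (int j = i + 1; j < nh; ++j) M(i, j) = M(j, i);
  }
  return M;
}
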