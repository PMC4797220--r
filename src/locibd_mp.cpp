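#include <Rcpp.h>
using namespace Rcpp;

// Multipoint locus-IBD matrix. For each pair and each window marker i with
// genetic distance d_i from the midpoint, a_i = exp(-2 T d_i) is the
// probability that an IBD segment at the midpoint still covers marker i.
// Under midpoint-IBD a marker is IBS with probability a_i + (1 - a_i) h_i,
// under non-IBD with probability h_i (population homozygosity). Treating
// markers as independent, the likelihood ratio R multiplies per-marker
// factors (a_i + (1 - a_i) h_i) / h_i for IBS markers and (1 - a_i) for
// non-IBS markers, and the posterior is p = phi R / (phi R + 1 - phi).
// lr1 / lr0 are the per-marker log-factors, precomputed per window.
// [[Rcpp::export]]
NumericMatrix locibd_fill_mp(const IntegerMatrix& H, const IntegerVector& cols,
                             const NumericVector& lr1, const NumericVector& lr0,
                             double phi) {
  const int nh = H.nrow();
  const int nc = cols.size();
  std::vector<const int*> cp(nc);
  for (int t = 0; t < nc; ++t) cp[t] = &H(0, cols[t] - 1);
  NumericMatrix M(nh, nh);
  const double lodds = std::log(phi / (1.0 - phi));
  for (int i = 0; i < nh - 1; ++i) {
    double* Mi = &M(0, i);
    for (int j = i + 1; j < nh; ++j) {
      double lr = lodds;
      for (int t = 0; t < nc; ++t)
        lr += (cp[t][i] == cp[t][j]) ? lr1[t] : lr0[t];
      Mi[j] = 1.0 / (1.0 + std::exp(-lr));
    }
  }
  for (int i = 0; i < nh; ++i) {
    M(i, i) = 1.0;
    for (int j = i + 1; j < nh; ++j) M(i, j) = M(j, i);
  }
  return M;
}
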