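#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Rogers distances on an additive-coded, imputed genotype matrix.
// Input is markers x lines (transposed) so each line is one contiguous
// column. For fully specified within-line allele frequencies p = (1+x)/2,
// the per-locus Rogers term sqrt(0.5 * ((p_i-p_j)^2 + (q_i-q_j)^2))
// collapses to |x_i - x_j| / 2, so the distance is the mean absolute
// coded difference over markers, halved.
// [[Rcpp::export]]
NumericMatrix rogers_dist_cpp(NumericMatrix tX) {
  const int m = tX.nrow();
  const int n = tX.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &tX(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double* xj = &tX(0, j);
      double s = 0.0;
      for (int l = 0; l < m; ++l) s += std::fabs(xi[l] - xj[l]);
      const double d = s / (2.0 * m);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
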