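#include <Rcpp.h>
using namespace Rcpp;

// Henderson tabular numerator relationship matrix with inbreeding.
// sire/dam are 0-based row indices into the (topologically sorted)
// pedigree, or -1 when unknown. a_ij = 0.5 (a_{s(i),j} + a_{d(i),j})
// for j < i; a_ii = 1 + 0.5 a_{s(i),d(i)}.
// [[Rcpp::export]]
NumericMatrix nrm_tabular(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s >= i || d >= i)
      stop("pedigree not topologically sorted at row %d", i + 1);
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(s, j);
      if (d >= 0) a += 0.5 * A(d, j);
      A(i, j) = A(j, i) = a;
    }
    A(i, i) = 1.0 + (s >= 0 && d >= 0 ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}
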