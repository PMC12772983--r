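#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy (Richman & Moorman convention):
// both template lengths are counted over the same n - m offsets, so every
// length-m template has an (m+1)-extension.  B = unordered pairs of
// length-m templates within Chebyshev distance r, A = pairs also matching
// at the (m+1)-th component; self-matches excluded.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) stop("need at least m + 2 samples");
  long double A = 0, B = 0;
  const int nt = n - m;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = x[i + k] - x[j + k];
        if (d < 0) d = -d;
        if (d > r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      double d = x[i + m] - x[j + m];
      if (d < 0) d = -d;
      if (d <= r) ++A;
    }
  }
  return NumericVector::create((double)B, (double)A);
}
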