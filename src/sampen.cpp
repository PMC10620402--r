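#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman).
// B counts pairs (i < j), i,j in 0..n-m-1, whose length-m templates
// match within tolerance r under the Chebyshev distance; A counts the
// same pairs matching at length m+1. Self-matches are excluded by
// construction.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;            // usable template starts
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
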