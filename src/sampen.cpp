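#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy: -log(A/B) with B = #pairs of templates of length m
// matching within tolerance r (Chebyshev distance), A = same for m+1.
// Self-matches excluded.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  long double a = 0, b = 0;
  int nm = n - m;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++b;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r) ++a;
    }
  }
  if (b == 0 || a == 0) return NA_REAL;
  return -std::log((double)(a / b));
}
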