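#include <Rcpp.h>
using namespace Rcpp;

// Lexicographic rank (Lehmer code) of the rank-string of each sliding window.
// Rank-string entry s_j is the rank of w_j within the window, ties broken so
// the earlier sample ranks lower.  The Lehmer digit of position j is then
// #{k > j : w_k < w_j} (strict: an equal later value ranks higher), and the
// pattern index is sum_j d_j * (D-1-j)!.

// [[Rcpp::export]]
IntegerVector ordinal_codes_cpp(NumericVector x, int D, int lag) {
  const int n = x.size();
  if (D < 2 || D > 8) stop("pattern length D must be in [2, 8]");
  if (lag < 1) stop("lag must be >= 1");
  const int span = (D - 1) * lag;
  if (n < span + 1)
    stop("series too short: need at least (D-1)*lag + 1 = %d samples, got %d",
         span + 1, n);
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("non-finite value at position %d", i + 1);

  int fact[9];
  fact[0] = 1;
  for (int j = 1; j <= 8; ++j) fact[j] = fact[j - 1] * j;

  const int m = n - span;
  IntegerVector codes(m);
  for (int t = 0; t < m; ++t) {
    int code = 0;
    for (int j = 0; j < D - 1; ++j) {
      const double wj = x[t + j * lag];
      int d = 0;
      for (int k = j + 1; k < D; ++k)
        if (x[t + k * lag] < wj) ++d;
      code += d * fact[D - 1 - j];
    }
    codes[t] = code;
  }
  return codes;
}
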