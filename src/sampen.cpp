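#include <Rcpp.h>

// Sample entropy by direct template counting (Chebyshev distance,
// self-matches included). Both template lengths use the same index range
// i = 0 .. N-m-1 so that the length-(m+1) template always exists; with
// self-matches included B >= N-m > 0 and A >= N-m > 0, so the ratio is
// always defined for r >= 0.
//
// The count is symmetric in (i, j), so only ordered pairs j > i are
// visited; totals are 2 * count + (N - m) self-matches.
// [[Rcpp::export]]
double sampen_count_cpp(const Rcpp::NumericVector& x, int m, double r) {
  const int N = x.size();
  const int M = N - m;
  long long A = 0, B = 0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int t = 0; t < m; ++t) {
        const double a = std::fabs(x[i + t] - x[j + t]);
        if (a > d) d = a;
        if (d > r) {
          ok = false;
          break;
        }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  const long long At = 2 * A + M, Bt = 2 * B + M;
  if (Bt == 0) return NA_REAL;
  if (At == 0) return R_PosInf;
  return -std::log(static_cast<double>(At) / static_cast<double>(Bt));
}
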