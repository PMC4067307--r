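#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two integer-coded sequences with
// linear gap penalty and deterministic tie-breaking: diagonal > up > left.
// Returns the optimal score, the number of identical aligned pairs on the
// traceback path, and the alignment length (columns, gaps included).
// [[Rcpp::export(name = ".nw_align_c")]]
List nw_align_c(IntegerVector a, IntegerVector b,
                double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty genome");
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);     // 0 diag, 1 up (gap in b), 2 left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double best = d; int ptr = 0;
      if (u > best) { best = u; ptr = 1; }
      if (l > best) { best = l; ptr = 2; }
      S(i, j) = best; P(i, j) = ptr;
    }
  }
  int i = n, j = m, matches = 0, len = 0;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (i > 0 && j > 0 && ptr == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (ptr == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++len;
  }
  return List::create(_["score"] = S(n, m), _["matches"] = matches,
                      _["length"] = len);
}
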