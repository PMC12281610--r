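#include <Rcpp.h>
using namespace Rcpp;

// Single-end quality trimming over Phred+33 quality strings, applying in
// order: LEADING (drop 5' bases with q < leading_q), TRAILING (drop 3'
// bases with q < trailing_q), SLIDINGWINDOW (scan full windows 5'->3'; cut
// the read just before the first window whose mean quality drops below
// window_q, then clip remaining 3' bases individually below window_q),
// MINLEN (drop reads shorter than min_len). Returns 1-based [start, end]
// per read; start = 0 marks a dropped read.
// [[Rcpp::export]]
IntegerMatrix trim_bounds_cpp(CharacterVector quals, int leading_q,
                              int trailing_q, int window_size, double window_q,
                              int min_len) {
  const int n = quals.size();
  IntegerMatrix bounds(n, 2);
  for (int r = 0; r < n; ++r) {
    SEXP el = STRING_ELT(quals, r);
    const char *s = CHAR(el);
    const int L = LENGTH(el);
    int a = 0, b = L - 1;
    while (a <= b && s[a] - 33 < leading_q) ++a;
    while (b >= a && s[b] - 33 < trailing_q) --b;
    if (a <= b && b - a + 1 >= window_size) {
      double thr = window_q * window_size;
      long sum = 0;
      for (int k = a; k < a + window_size; ++k) sum += s[k] - 33;
      int w = a;
      while (true) {
        if ((double)sum < thr) {  // strict: cut before this window
          b = w - 1;
          break;
        }
        if (w + window_size > b) break;
        sum += s[w + window_size] - 33;
        sum -= s[w] - 33;
        ++w;
      }
    }
    while (b >= a && (double)(s[b] - 33) < window_q) --b;
    if (b - a + 1 < min_len || a > b) {
      bounds(r, 0) = 0;
      bounds(r, 1) = -1;
    } else {
      bounds(r, 0) = a + 1;
      bounds(r, 1) = b + 1;
    }
  }
  return bounds;
}
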