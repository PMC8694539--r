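#include <Rcpp.h>

// Exhaustive-history LZ76 parsing count (Kaspar-Schuster scan).
// A new phrase is opened whenever the upcoming symbol extends beyond the
// longest substring reproducible from the extended history.
// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(Rcpp::IntegerVector bits) {
  const int n = bits.size();
  if (n == 0) Rcpp::stop("empty sequence");
  if (n == 1) return 1;
  int c = 1, i = 0, k = 1, l = 1, kmax = 1;
  for (;;) {
    if (bits[i + k - 1] != bits[l + k - 1]) {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) {
        ++c;
        break;
      }
    }
  }
  return c;
}
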