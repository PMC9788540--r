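#include <Rcpp.h>
using namespace Rcpp;

// Best gap-free antisense duplex between a (reversed) sRNA and a target
// window. rq and w are 1..4 codes (A,C,G,U; NA = ambiguous), smat the 4x4
// pair-score matrix. A maximal complementary run qualifies when it contains
// at least seed_min consecutive pairs; its score is the sum of pair scores.
// Returns c(score, i0, i1, j0, j1) with 1-based coordinates on rq and w,
// or score -1 when no run qualifies.

// [[Rcpp::export]]
NumericVector duplex_scan(IntegerVector rq, IntegerVector w,
                          NumericMatrix smat, int seed_min) {
  int m = rq.size(), n = w.size();
  double best = -1.0;
  int bi0 = 0, bi1 = 0, bj0 = 0, bj1 = 0;
  for (int d = -(m - 1); d <= n - 1; ++d) {
    int i = d < 0 ? -d + 1 : 1;
    int j = d < 0 ? 1 : d + 1;
    double run = 0.0;
    int runlen = 0, ri = 0, rj = 0;
    while (i <= m && j <= n) {
      int a = rq[i - 1], b = w[j - 1];
      double s = (a == NA_INTEGER || b == NA_INTEGER) ? 0.0 : smat(a - 1, b - 1);
      if (s > 0) {
        if (runlen == 0) { ri = i; rj = j; }
        run += s;
        ++runlen;
        if (i == m || j == n) {
          if (runlen >= seed_min && run > best) {
            best = run; bi0 = ri; bi1 = i; bj0 = rj; bj1 = j;
          }
        }
      } else if (runlen > 0) {
        if (runlen >= seed_min && run > best) {
          best = run; bi0 = ri; bi1 = i - 1; bj0 = rj; bj1 = j - 1;
        }
        run = 0.0;
        runlen = 0;
      }
      ++i; ++j;
    }
  }
  return NumericVector::create(best, bi0, bi1, bj0, bj1);
}
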