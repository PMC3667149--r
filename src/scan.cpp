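#include <Rcpp.h>
using namespace Rcpp;

// Additive sliding-window scores for a 4 x w weight matrix over an
// integer-encoded sequence (0..3 = A,C,G,T; negative = ineligible).
// Windows containing an ineligible base score NA.
// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector seq, NumericMatrix W) {
  int n = seq.size(), w = W.ncol();
  int nw = n - w + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  for (int o = 0; o < nw; ++o) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int b = seq[o + j];
      if (b < 0) { ok = false; break; }
      s += W(b, j);
    }
    out[o] = ok ? s : NA_REAL;
  }
  return out;
}

// Count of windows scoring >= thr and the best window score; used for
// bulk scanning where per-hit detail is not needed.
// [[Rcpp::export]]
NumericVector cpp_scan_stats(IntegerVector seq, NumericMatrix W, double thr) {
  int n = seq.size(), w = W.ncol();
  int count = 0;
  double best = R_NegInf;
  for (int o = 0; o + w <= n; ++o) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int b = seq[o + j];
      if (b < 0) { ok = false; break; }
      s += W(b, j);
    }
    if (!ok) continue;
    if (s > best) best = s;
    if (s >= thr) ++count;
  }
  return NumericVector::create(count, best);
}
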