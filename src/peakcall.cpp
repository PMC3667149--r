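#include <Rcpp.h>
using namespace Rcpp;

// Qualified enriched regions at one absolute cutoff.
//
// pos: sorted probe start positions for one chromosome; ratio: matching
// log2 ratios. A cluster is a maximal set of above-cutoff probes whose
// consecutive gaps are <= window bp. The cluster qualifies when
//  (a) some min_probes consecutive above-cutoff probes span < window bp, or
//  (b) some run of >= min_all consecutive track probes are all above cutoff
//      (no below-cutoff probe in between).
// Returns a 2-column matrix of [first above-probe pos, last above-probe pos]
// per qualified cluster (the R wrapper extends the right edge by one
// probe spacing).
// [[Rcpp::export]]
NumericMatrix cpp_regions_at_cutoff(NumericVector pos, NumericVector ratio,
                                    double cutoff, double window,
                                    int min_probes, int min_all) {
  int n = pos.size();
  std::vector<int> ab;
  ab.reserve(n / 4 + 1);
  for (int i = 0; i < n; ++i)
    if (ratio[i] > cutoff) ab.push_back(i);
  int na = ab.size();
  std::vector<double> out;
  int cs = 0;  // cluster start (index into ab)
  for (int k = 1; k <= na; ++k) {
    bool split = (k == na) || (pos[ab[k]] - pos[ab[k - 1]] > window);
    if (!split) continue;
    // cluster = ab[cs .. k-1]
    bool ok = false;
    int m = k - cs;
    if (m >= min_probes) {
      for (int i = cs; i + min_probes - 1 <= k - 1 && !ok; ++i)
        if (pos[ab[i + min_probes - 1]] - pos[ab[i]] < window) ok = true;
    }
    if (!ok && m >= min_all) {
      int run = 1;
      for (int i = cs + 1; i <= k - 1 && !ok; ++i) {
        run = (ab[i] == ab[i - 1] + 1) ? run + 1 : 1;
        if (run >= min_all) ok = true;
      }
      if (!ok && min_all <= 1 && m >= 1) ok = true;
    }
    if (ok) {
      out.push_back(pos[ab[cs]]);
      out.push_back(pos[ab[k - 1]]);
    }
    cs = k;
  }
  int nr = out.size() / 2;
  NumericMatrix res(nr, 2);
  for (int r = 0; r < nr; ++r) {
    res(r, 0) = out[2 * r];
    res(r, 1) = out[2 * r + 1];
  }
  return res;
}
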