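#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-occurrence-per-sequence Gibbs site sampler.
//
// seqs: list of integer vectors (0..3 = A,C,G,T; negative = ineligible).
// Sites on the minus strand contribute their reverse complement to the
// motif counts. Uses R's RNG so set.seed() in R makes runs reproducible.

static inline int comp(int b) { return 3 - b; }

// add/remove a site's contribution to counts (4 x w)
static void add_site(std::vector<double>& counts, const IntegerVector& s,
                     int off, int strand, int w, double sign) {
  for (int j = 0; j < w; ++j) {
    int b = (strand == 0) ? s[off + j] : comp(s[off + w - 1 - j]);
    counts[4 * j + b] += sign;
  }
}

// motif score F = sum_j sum_b c(j,b) * log(q(j,b) / p(b))
static double state_score(const std::vector<double>& counts, int w, int nseq,
                          const NumericVector& bg, double pseudo) {
  double F = 0.0;
  for (int j = 0; j < w; ++j) {
    for (int b = 0; b < 4; ++b) {
      double c = counts[4 * j + b];
      double q = (c + pseudo * bg[b]) / (nseq + pseudo);
      if (c > 0) F += c * std::log(q / bg[b]);
    }
  }
  return F;
}

// [[Rcpp::export]]
List cpp_gibbs(List seqs, int width, int iterations, NumericVector bg,
               double pseudo, int phase_every) {
  int n = seqs.size();
  std::vector<IntegerVector> S(n);
  std::vector<int> maxoff(n);
  for (int i = 0; i < n; ++i) {
    S[i] = as<IntegerVector>(seqs[i]);
    maxoff[i] = S[i].size() - width;
    if (maxoff[i] < 0) stop("sequence shorter than motif width");
  }
  std::vector<int> off(n), strand(n);
  std::vector<double> counts(4 * width, 0.0);
  for (int i = 0; i < n; ++i) {
    off[i] = (int)std::floor(unif_rand() * (maxoff[i] + 1));
    if (off[i] > maxoff[i]) off[i] = maxoff[i];
    strand[i] = (unif_rand() < 0.5) ? 0 : 1;
    add_site(counts, S[i], off[i], strand[i], width, 1.0);
  }
  double init_score = state_score(counts, width, n, bg, pseudo);
  double best = init_score;
  std::vector<int> best_off(off), best_strand(strand);

  std::vector<double> q(4 * width), wts;
  for (int it = 1; it <= iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      add_site(counts, S[i], off[i], strand[i], width, -1.0);
      for (int j = 0; j < width; ++j)
        for (int b = 0; b < 4; ++b)
          q[4 * j + b] = (counts[4 * j + b] + pseudo * bg[b]) /
                         (n - 1 + pseudo);
      int K = maxoff[i] + 1;
      wts.assign(2 * K, 0.0);
      double tot = 0.0;
      const IntegerVector& s = S[i];
      for (int o = 0; o < K; ++o) {
        double wf = 1.0, wr = 1.0;
        bool ok = true;
        for (int j = 0; j < width; ++j) {
          int b = s[o + j];
          if (b < 0) { ok = false; break; }
          wf *= q[4 * j + b] / bg[b];
          int br = comp(s[o + width - 1 - j]);
          wr *= q[4 * j + br] / bg[br];
        }
        if (!ok) { wf = 0.0; wr = 0.0; }
        wts[o] = wf;
        wts[K + o] = wr;
        tot += wf + wr;
      }
      int pick;
      if (tot <= 0.0) {
        pick = (int)std::floor(unif_rand() * 2 * K);
      } else {
        double u = unif_rand() * tot, acc = 0.0;
        pick = 2 * K - 1;
        for (int k = 0; k < 2 * K; ++k) {
          acc += wts[k];
          if (u <= acc) { pick = k; break; }
        }
      }
      off[i] = pick % K;
      strand[i] = pick / K;
      add_site(counts, S[i], off[i], strand[i], width, 1.0);
    }
    double F = state_score(counts, width, n, bg, pseudo);
    if (F > best) {
      best = F;
      best_off = off;
      best_strand = strand;
    }
    // phase-shift move: slide every site by d, keep if the score improves
    if (phase_every > 0 && it % phase_every == 0) {
      for (int d = -3; d <= 3; ++d) {
        if (d == 0) continue;
        bool feasible = true;
        for (int i = 0; i < n && feasible; ++i) {
          int o = off[i] + (strand[i] == 0 ? d : -d);
          if (o < 0 || o > maxoff[i]) feasible = false;
        }
        if (!feasible) continue;
        std::vector<double> c2(4 * width, 0.0);
        std::vector<int> o2(n);
        for (int i = 0; i < n; ++i) {
          o2[i] = off[i] + (strand[i] == 0 ? d : -d);
          add_site(c2, S[i], o2[i], strand[i], width, 1.0);
        }
        double F2 = state_score(c2, width, n, bg, pseudo);
        if (F2 > F) {
          off = o2;
          counts = c2;
          F = F2;
          if (F > best) { best = F; best_off = off; best_strand = strand; }
        }
      }
    }
  }
  // counts of the best state
  std::vector<double> bc(4 * width, 0.0);
  for (int i = 0; i < n; ++i)
    add_site(bc, S[i], best_off[i], best_strand[i], width, 1.0);
  NumericMatrix cm(4, width);
  for (int j = 0; j < width; ++j)
    for (int b = 0; b < 4; ++b) cm(b, j) = bc[4 * j + b];
  return List::create(_["offsets"] = wrap(best_off),
                      _["strands"] = wrap(best_strand),
                      _["counts"] = cm,
                      _["score"] = best,
                      _["initial_score"] = init_score);
}
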