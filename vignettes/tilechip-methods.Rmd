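---
title: "tilechip: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilechip: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the peak-calling model and its permutation FDR, the
annotation and profile conventions, the Gibbs motif sampler, the
PWM-enrichment test, and the synthetic-study generator that all of the
package's benchmarks run on. It also records the numerical choices and
the places where the design was genuinely open.

## 1. The substrate: probe-level log2 ratios

A ChIP-chip tiling array reports, for probes spaced ~100 bp apart, the
base-2 logarithm of the ratio between the immunoprecipitated sample and
a control. `tilechip` starts at these log2 ratios — there is no
two-channel normalization, replicate merging or probe remapping in
scope. Internally every coordinate is 0-based half-open (BED-like);
1-based conventions (GFF, WIG) are converted only at the I/O boundary,
so interval arithmetic never branches on off-by-one cases.

## 2. Cutoff-ladder peak calling

The detector mirrors the standard tiling-array parameterization:

* **Hypothetical maximum** `H = mean(r) + k·sd(r)` per chromosome
  (population sd, `k = 6`). This is the scaling anchor for the ladder;
  `k` is exposed because the anchor definition is a convention, not a
  derived quantity.
* **Ladder**: cutoffs `(p_start − i·p_step)/100 · H` for
  `i = 0..n_steps−1`; defaults 90%, 89%, ..., 15% (76 rungs).
* **Qualification at one cutoff**: above-cutoff probes closer than the
  500 bp window are clustered; a cluster qualifies when some 500 bp
  window holds ≥ 4 above-cutoff probes, *or* when ≥ 2 consecutive
  track probes are above the cutoff with no below-cutoff probe between
  them. The second rule is the natural reading of the printed
  "when all probes in peak > cutoff = 2" setting; both thresholds are
  parameters. A qualifying cluster spans from its first above-cutoff
  probe start to its last above-cutoff probe start plus one probe
  spacing; sub-probe boundary resolution is not attempted.
* **Scoring**: rungs are processed from the top; regions from lower
  rungs that overlap an existing peak extend its boundaries but keep
  the higher score, so a peak's score is the highest rung at which any
  sub-region of it qualifies. The final peak set is therefore the
  connected components of the union of all qualifying regions — a fact
  the test suite exploits by checking the incremental implementation
  against an independent per-probe score-painting oracle.

### Permutation FDR and its honest limits

The FDR estimator shuffles the ratio values over the fixed probe
positions (per chromosome), re-calls peaks down the same ladder
`n_permutations = 20` times, and sets
`FDR(s) = mean permuted count of peaks scoring ≥ s / observed count`,
clipped to [0, 1] and made monotone non-increasing in `s` (cumulative
maximum down the ladder). Peaks are filtered at the strict
`FDR < 0.005`. The estimator is deterministic given the seed.

This design preserves the probe geometry and the marginal intensity
distribution, but it has a structural conservatism that users should
understand. When a track genuinely contains enriched regions, the
shuffle scatters the enriched probe values across the chromosome, and
any *pair* of them landing on adjacent probes qualifies under the
2-consecutive-probes rule. The expected number of such permuted peaks
at cutoff `c` is approximately `n·(f·P(signal > c))²` for `n` probes
and a planted-probe fraction `f` — about 0.2–5 per permutation at every
rung of the default benchmark, and invariant to rescaling the
enrichment because the ladder scales with it. The raw FDR therefore
has a floor of roughly 0.01–0.05 at any rung that retains a meaningful
share of the true peaks, and the strict 0.005 filter keeps only the few
top-rung peaks that no permutation can reach. On the default synthetic
scenario (enrichment mean 2, noise sd 0.5) the filter's sensitivity is
accordingly a few percent, with an essentially zero false-discovery
proportion; relaxing the threshold to the estimator's floor (≈ 0.05),
raising the enrichment-to-noise ratio, or dropping the 2-probe rule
(at the cost of all peaks shorter than 4 probes) are the available
remedies, and all are one parameter away. On *pure-noise* tracks the
estimator is calibrated: the only way a noise peak survives the strict
filter is for the observed track's top-scoring peak to out-score all 20
permutations, an exchangeability event of probability ≈ 1/21, so ~95%
of null tracks yield zero surviving peaks — the package's
`null_calibration_benchmark()` measures exactly this.

## 3. Annotation conventions

Each peak is represented by its midpoint `floor((start+end)/2)` — a
peak must be counted exactly once in category summaries, which forces a
point representation. Categories are assigned with precedence
`promoter > tes > coding > exon > intron > intergenic`:

* *promoter*: within 10 kb strictly upstream of a TSS, strand-oriented;
* *tes*: from the TES base to 10 kb downstream (the TES window size is
  assumed symmetric with the promoter window);
* *coding*: exonic bases inside the CDS span (CDS introns excluded);
* *exon*: non-CDS exonic bases; *intron*: gene body minus exons.

The per-base masks built under this precedence are the single source of
truth: `assign_category()` looks peak midpoints up in them, and the
synthetic generator samples planted-peak midpoints from them, so
planted categories are recovered exactly by construction. Peak-to-gene
links use a different, two-sided window: midpoint within ±10 kb of the
TSS (closed at both ends), signed offsets oriented by the gene's
strand. TSS = transcript start for `+` genes and the last transcript
base for `−` genes; TES is the opposite end.

## 4. Gibbs motif discovery

The sampler is the classical one-occurrence-per-sequence site sampler:
one candidate site (offset and strand) per sequence; per sweep each
sequence's site is resampled with probability proportional to the
PWM/background likelihood ratio, where the PWM is rebuilt from all
*other* sites with Dirichlet pseudocounts `1.0 × background` per
column and the background is the 0-order composition of the input. The
motif score is `F = Σ_cols Σ_bases c·log(q/p)`; the best-scoring state
over all sweeps is returned, which guarantees the result is at least as
good as the random initialization. Every 100 sweeps a phase-shift move
tries sliding all sites by ±1..3 and keeps an improvement, to escape
phase-locked optima. Motif orientation is unidentifiable when sites
occur on both strands, so recovery comparisons score the discovered PWM
against the truth in both orientations.

Occupancy ("fraction of peaks containing the motif") is computed by
scanning: a sequence counts when its best log-odds window on either
strand reaches `threshold_fraction = 0.8` of the maximal achievable
log-odds. Threshold fractions above 1 are clamped to 1, where only
exact consensus matches count. Because planted-but-degenerate instances
can fall below a high threshold, occupancy benchmarks plant the
consensus word and subtract a matched rate-zero control's fraction.

## 5. PWM enrichment and consensus scanning

PWM scanning uses the Match-style information-weighted similarity:
column weights `I(i) = Σ_b f(i,b)·ln(4 f(i,b))`, window score
`Σ I(i)·f(i, b_i)`, min–max normalized so the per-column argmax word
scores exactly 1. A single global threshold (0.85) replaces per-matrix
profile thresholds, which are proprietary conventions of the original
tool; it is recorded in outputs. Windows containing non-ACGT letters
are ineligible everywhere (scans, GC computation, motif matching).

Controls are drawn per peak and per set: same length, same chromosome,
uniform placement, rejection-sampled away from any peak (overlap would
dilute the null). Enrichment per matrix is the one-cell goodness-of-fit
chi-square `(O − E)²/E` on 1 df, with `O` the total hit count over
peaks and `E` the mean total over the ten control sets; "total" counts
all occurrences by default (a capped per-sequence mode is a flag), a
2×2 variant is behind a flag, and no multiple-testing correction is
applied by default because the workflow reports raw `p < 0.0005`
(Bonferroni is a flag). With ten control sets the variance inflation of
`O − E` is only 1.1×, so the raw chi-square stays close to calibrated —
the acceptance benchmark bounds the aggregate null false-positive count
at twice the nominal alpha.

The degenerate consensus scanner parses bracket expressions (e.g. the
9-mer CTCF motif `AG[GA][GT]GG[CAT][GAT][CG]`, 72 words, 144 with
reverse complements), converts them to IUPAC strings and counts
overlapping matches exactly via Biostrings; a regular-expression oracle
cross-checks it in the tests.

## 6. Profiles, DE intersection, DHS co-occurrence

Expression strata are rank splits (top 30% / middle 40% / bottom 30%,
ceilings, ties broken by gene id). Metaprofiles histogram signed
strand-oriented midpoint offsets in [−10 kb, 10 kb) into 200 bp bins
(the bin width is a package choice; the source material does not print
one) and normalize by the group's gene count; a peak near two genes
contributes an event to each, which the per-gene orientation forces.
DE intersection takes each TSS-linked gene once and applies the signed
fold-change threshold ±1.5. DHS co-occurrence flags a peak when any
DHS interval overlaps `[start − 1 kb, end + 1 kb)`, half-open.

## 7. The synthetic-study generator

The generator's defaults are the study conditions every benchmark runs
under: 3 chromosomes × 2 Mb, GC 0.41, 100 genes, probes every 100 bp
(50-mers), 100 planted peaks with mean length 692 bp (shifted geometric
with minimum 2 probe spacings — only the mean is prescribed, so the
simplest non-negative law with that mean is used), in-peak probe ratios
`N(2.0, 0.5)` on a flat plateau over `N(0, 0.5)` background (the
minimal signal model the cutoff-ladder caller assumes), a 55% per-peak
motif plant rate, a 13.44% DHS co-occurrence rate, and 26 up / 47 down
differentially expressed genes at signed fold change ±1.5.

Choices the generator makes where the emulated study is silent:

* **Category proportions** default to promoter .10, intron .45,
  exon .03, coding .02, TES .10, intergenic .18; the remaining 12% is
  an explicit *unlabeled* remainder (the emulated category breakdown
  does not sum to 100%), placed in a uniformly chosen feature category.
  Per-category counts use largest-remainder apportionment, so the
  planted mix is exact and recovery tests measure the annotator, not
  multinomial noise. Uniform placement of the remainder adds ~2
  percentage points to each category — within the ±3-point recovery
  tolerance by design.
* **Gene architecture**: ~24–36 kb transcripts, 4–8 exons covering
  ~55–65% of the body, CDS spanning the central half of the exonic
  bases, ≥ 15 kb intergenic gaps, ~half of genes per strand. This is
  chosen to give a roughly *balanced* per-base category composition on
  a compact genome — deliberately not human-like exon statistics, which
  would make coding/exon peaks almost unplaceable at this scale.
* **Peak spacing**: planted peaks stay ≥ 2.5 kb apart so each DHS
  flag is unambiguous (a near-peak DHS can never sit within 1 kb of a
  *different* peak, which would otherwise inflate co-occurrence).
* **Expression**: log-normal levels (heavy-tailed, ties have
  probability zero, so tertile splits are unambiguous); null genes get
  signed fold changes with magnitude in [1, 1.5), up/down genes
  1.5 + Exp(2) beyond the threshold.
* **Determinism**: one master seed is expanded into fixed per-stage
  seeds, so any stage can be rerun independently and the whole study is
  byte-identical under the same configuration.

What the generator does *not* emulate: spatial autocorrelation of
chromatin domains, probe GC/affinity biases, raw two-channel
fluorescence, or replicate structure. Passing benchmarks on it
therefore demonstrates the correctness and calibration of the
algorithms under their own assumptions — flat enrichment plateaus and
i.i.d. Gaussian noise — not performance on real arrays, where
correlated noise typically makes permutation FDRs optimistic rather
than conservative.

## 8. Benchmark problem sizes

The shipped benchmarks use: 200 random ≤ 200-probe tracks for oracle
equivalence; 10 default-scenario seeds for peak recovery; 50 pure-noise
1 Mb tracks (10,000 probes) for null calibration; 2,000 planted peaks
on 3 × 8 Mb for category recovery; 200 × 500 bp sequences, plant rate
0.8, column identity 0.9, 1,000 sampler iterations × 5 seeds for motif
recovery; 300-peak power and 50 × 20-matrix null replicates for
enrichment; 5,000 peaks on 3 × 30 Mb (coordinate-only, no sequence) for
DHS co-occurrence, sized so far-DHS placement ≥ 5 kb from any peak
stays feasible; and two full default pipeline runs for determinism.
These sizes are the package's own benchmark scales, chosen to keep a
full check run in minutes while leaving every estimate's sampling error
well inside the asserted tolerances.

## 9. Known limitations

* The permutation FDR's conservatism on signal-rich tracks (section 2)
  is inherent to ratio shuffling combined with the 2-consecutive-probe
  rule; users wanting high recall at tiling-array scale should filter
  at the estimator's floor or use the score rungs directly.
* The peak score is reported as the ladder rung percentage; whether the
  original array software transformed it further is not recoverable,
  so downstream code should treat scores as ordinal.
* Match-style scanning with one global threshold trades the original
  per-matrix error profiles for transparency; enrichment rankings are
  robust to this, absolute hit counts are not.
* `fraction_with_motif` measures thresholded presence, not binding
  affinity; its background depends on motif information content, which
  is why benchmarks subtract a matched control.
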