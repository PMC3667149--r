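Package: tilechip
Title: Tiling-Array ChIP Peak Calling, Motif Discovery and Regulatory
    Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for histone-modification
    ChIP-chip tiling-array data: sliding-window cutoff-ladder peak
    detection on probe log2-ratio tracks with permutation-estimated
    false discovery rates, peak-to-feature annotation and chromosome
    density tracks, fixed-width Gibbs-sampling motif discovery,
    position-weight-matrix scanning with randomized-control chi-square
    enrichment, degenerate consensus (CTCF-style) occupancy scanning,
    expression-stratified TSS metaprofiles, differential-expression
    intersection and DNase-hypersensitivity co-occurrence. A fully
    self-contained synthetic-study generator (genome, gene models,
    probe tracks with planted enrichment, motifs, expression and DHS
    intervals, plus a truth ledger) supports benchmarking of every
    stage, and a pipeline driver orchestrates a reproducible run from
    a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
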