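#' Peak-recovery benchmark on the default synthetic scenario
#'
#' For each seed, simulates the standard study (3 x 2 Mb, 100 bp
#' spacing, 100 planted peaks of mean length 692, enrichment mean 2.0,
#' noise sd 0.5), calls peaks down the full ladder, estimates the
#' permutation FDR and filters at `fdr_max`. Sensitivity is the
#' fraction of planted peaks overlapped by at least one filtered peak;
#' the false-discovery proportion (FDP) is the fraction of filtered
#' peaks overlapping no planted peak (0 when nothing is filtered).
#'
#' @param seeds integer vector of generator seeds.
#' @param config_fn function(seed) returning a [synth_config()].
#' @param params a [peak_params()] template (its seed is re-derived per
#'   run).
#' @param fdr_max strict FDR filter threshold.
#' @return data.frame (seed, n_called, n_filtered, sensitivity, fdp,
#'   mean_called_length).
#' @export
peak_recovery_benchmark <- function(seeds = 1:10,
                                    config_fn = function(s)
                                      synth_config(seed = s),
                                    params = peak_params(),
                                    fdr_max = 0.005) {
  rows <- lapply(seeds, function(s) {
    cfg <- config_fn(s)
    lens <- setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                     paste0("chr", seq_len(cfg$n_chromosomes)))
    genes <- generate_gene_models(lens, cfg)
    pl <- plant_enrichment(lens, genes, cfg)
    track <- simulate_probe_track(lens, pl$peaks, cfg)
    params$seed <- derive_seed(s, "fdr-benchmark")
    called <- call_peaks(track, params)
    called <- estimate_fdr(track, called, params)
    kept <- filter_peaks(called, fdr_max)
    overlaps <- function(a, b) {
      vapply(seq_len(nrow(a)), function(i) {
        any(b$chrom == a$chrom[i] & b$start < a$end[i] &
              b$end > a$start[i])
      }, logical(1))
    }
    sens <- if (nrow(pl$peaks)) mean(overlaps(pl$peaks, kept)) else NA
    fdp <- if (nrow(kept)) mean(!overlaps(kept, pl$peaks)) else 0
    data.frame(seed = s, n_called = nrow(called),
               n_filtered = nrow(kept), sensitivity = sens, fdp = fdp,
               mean_called_length =
                 if (nrow(called)) mean(called$end - called$start) else NA)
  })
  do.call(rbind, rows)
}

#' Null-calibration benchmark: peaks surviving the FDR filter on noise
#'
#' Pure-noise tracks (no planted enrichment) are called and filtered at
#' the strict FDR threshold; under a calibrated filter almost every
#' seed yields zero surviving peaks.
#'
#' @param seeds integer vector of seeds.
#' @param n_probes probes per track.
#' @param spacing probe spacing (bp).
#' @param sigma noise standard deviation (log2 units).
#' @param params a [peak_params()] template.
#' @param fdr_max strict FDR filter threshold.
#' @return integer vector: surviving peak count per seed.
#' @export
null_calibration_benchmark <- function(seeds = 1:50, n_probes = 10000,
                                       spacing = 100, sigma = 0.5,
                                       params = peak_params(),
                                       fdr_max = 0.005) {
  vapply(seeds, function(s) {
    track <- with_seed_if(s, {
      tr <- data.frame(chrom = "chr1",
                       start = spacing * (seq_len(n_probes) - 1),
                       ratio = rnorm(n_probes, 0, sigma),
                       stringsAsFactors = FALSE)
      attr(tr, "spacing") <- spacing
      tr
    })
    params$seed <- derive_seed(s, "null-benchmark")
    pk <- call_peaks(track, params)
    pk <- estimate_fdr(track, pk, params)
    nrow(filter_peaks(pk, fdr_max))
  }, numeric(1))
}
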