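#' Configuration for the synthetic ChIP-chip study generator
#'
#' The defaults describe the array substrate and planted-truth rates the
#' generator emulates: ~100 bp probe spacing, 50-mer probes, planted
#' enriched regions with a 692 bp mean length, a 55% per-peak motif
#' plant rate and a 13.44% DHS co-occurrence rate, with differential
#' expression defaulting to 26 up- and 47 down-regulated genes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param gc_content GC fraction of the background sequence, in (0,1).
#' @param n_genes number of gene models to place.
#' @param probe_spacing distance between probe starts (bp).
#' @param probe_length probe length (bp).
#' @param n_true_peaks number of planted enriched regions.
#' @param peak_length_mean mean planted peak length (bp); lengths follow
#'   a shifted geometric law with minimum `2 * probe_spacing`.
#' @param enrich_mu mean probe log2 ratio inside planted peaks.
#' @param noise_sigma standard deviation of probe log2 ratios.
#' @param motif_plant_rate per-peak probability of planting a motif.
#' @param dhs_overlap_rate fraction of peaks given a DHS within 1 kb.
#' @param de_up,de_down numbers of up-/down-regulated genes (signed fold
#'   change beyond +1.5 / -1.5).
#' @param category_props named category proportions for planted peaks;
#'   any mass missing from 1 is planted as an "unlabeled" remainder in a
#'   uniformly chosen feature category.
#' @param peak_min_gap minimum gap between planted peaks (bp); keeps
#'   per-peak DHS/motif truth flags unambiguous.
#' @param dhs_length length of simulated DHS intervals (bp).
#' @param seed integer seed driving every generator stage.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_chromosomes = 3,
                         chrom_length = 2e6,
                         gc_content = 0.41,
                         n_genes = 100,
                         probe_spacing = 100,
                         probe_length = 50,
                         n_true_peaks = 100,
                         peak_length_mean = 692,
                         enrich_mu = 2.0,
                         noise_sigma = 0.5,
                         motif_plant_rate = 0.55,
                         dhs_overlap_rate = 0.1344,
                         de_up = 26,
                         de_down = 47,
                         category_props = c(promoter = 0.10, intron = 0.45,
                                            exon = 0.03, coding = 0.02,
                                            tes = 0.10, intergenic = 0.18),
                         peak_min_gap = 2500,
                         dhs_length = 200,
                         seed = 1L) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              gc_content = gc_content, n_genes = n_genes,
              probe_spacing = probe_spacing, probe_length = probe_length,
              n_true_peaks = n_true_peaks,
              peak_length_mean = peak_length_mean, enrich_mu = enrich_mu,
              noise_sigma = noise_sigma,
              motif_plant_rate = motif_plant_rate,
              dhs_overlap_rate = dhs_overlap_rate,
              de_up = de_up, de_down = de_down,
              category_props = category_props,
              peak_min_gap = peak_min_gap, dhs_length = dhs_length,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c("n_chromosomes", "n_genes", "n_true_peaks", "de_up", "de_down")
  for (f in counts) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (cfg$chrom_length <= 0) stop("chrom_length must be positive")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) {
    stop("gc_content must lie in (0, 1)")
  }
  fracs <- c("motif_plant_rate", "dhs_overlap_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$probe_spacing < 1) stop("probe_spacing must be >= 1")
  if (cfg$peak_length_mean < cfg$probe_spacing) {
    stop("peak_length_mean must be >= probe_spacing")
  }
  if (any(cfg$category_props < 0) || sum(cfg$category_props) > 1 + 1e-8) {
    stop("category_props must be non-negative and sum to <= 1")
  }
  bad <- setdiff(names(cfg$category_props), FEATURE_CATEGORIES)
  if (length(bad)) stop("unknown category in category_props: ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_chromosomes, "x", x$chrom_length, "bp,",
      x$n_genes, "genes,", x$n_true_peaks, "planted peaks, seed",
      x$seed, "\n")
  invisible(x)
}
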