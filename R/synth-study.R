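#' Default planted motif: a synthetic G-rich 12-mer
#'
#' Stand-in target motif for the generator; G-rich, 12 bp wide, the
#' width the motif-discovery stage searches at by default.
#' @export
DEFAULT_MOTIF <- "GGGCGGGGGAGG"

#' Generate a complete synthetic study
#'
#' Runs every generator stage (genome, gene models, planted enrichment,
#' probe track, motif planting, expression / differential labels, DHS
#' intervals) and bundles the results with a truth ledger recording
#' every planted object exactly once.
#'
#' @param config a [synth_config()].
#' @param motif consensus string or [pwm()] to plant; NULL skips
#'   planting.
#' @return an object of class `synth_study`: list with genome, genes,
#'   peaks (planted), track, expression, dhs and `truth` (per-peak
#'   category, motif and DHS flags plus the per-gene DE table).
#' @export
simulate_study <- function(config = synth_config(), motif = DEFAULT_MOTIF) {
  stopifnot(inherits(config, "synth_config"))
  genome <- generate_genome(config)
  genes <- generate_gene_models(genome, config)
  planted <- plant_enrichment(genome, genes, config)
  track <- simulate_probe_track(genome, planted$peaks, config)
  if (!is.null(motif)) {
    pm <- plant_motifs(genome, planted$peaks, motif, config)
    genome <- pm$genome
    motif_flags <- pm$flags
  } else {
    motif_flags <- data.frame(peak_id = planted$peaks$peak_id,
                              planted = FALSE, offset = NA_real_,
                              strand = NA_character_)
  }
  expr <- simulate_expression_and_de(genes, config)
  dhs <- simulate_dhs(genome, planted$peaks, config)
  truth_peaks <- merge(merge(planted$truth, motif_flags, by = "peak_id"),
                       dhs$flags, by = "peak_id")
  truth_peaks <- truth_peaks[order(truth_peaks$chrom, truth_peaks$start), ]
  rownames(truth_peaks) <- NULL
  structure(list(config = config, genome = genome, genes = genes,
                 peaks = planted$peaks, track = track,
                 expression = expr, dhs = dhs$dhs,
                 truth = list(peaks = truth_peaks, de = expr)),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study>", length(x$genome), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$peaks), "planted peaks,",
      nrow(x$track), "probes\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits genome (FASTA), genes (GFF3 and BED12-like TSV), probe track
#' (fixedStep WIG and TSV), DHS (BED), expression (TSV) and the truth
#' ledger (TSV).
#'
#' @param study a `synth_study`.
#' @param outdir output directory (created if absent).
#' @return invisibly, named vector of written file paths.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(study$genome, p("genome.fa"))
  write_gff_genes(study$genes, p("genes.gff3"))
  write_genes_tsv(study$genes, p("genes.tsv"))
  write_wig(study$track, p("probes.wig"))
  write_probe_tsv(study$track, p("probes.tsv"))
  write_bed(study$dhs, p("dhs.bed"))
  write_expression_tsv(study$expression, p("expression.tsv"))
  write.table(study$truth$peaks, p("truth_peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(genome = p("genome.fa"), genes_gff = p("genes.gff3"),
             genes_tsv = p("genes.tsv"), wig = p("probes.wig"),
             probes = p("probes.tsv"), dhs = p("dhs.bed"),
             expression = p("expression.tsv"),
             truth = p("truth_peaks.tsv"))
  invisible(files)
}

## BED12-like flat gene table (exon block columns comma-separated).
write_genes_tsv <- function(genes, path) {
  df <- data.frame(
    chrom = genes$chrom, tx_start = genes$start, tx_end = genes$end,
    gene_id = genes$gene_id, score = 0, strand = genes$strand,
    cds_start = genes$cds_start, cds_end = genes$cds_end,
    n_exons = vapply(genes$exon_starts, length, integer(1)),
    exon_starts = vapply(genes$exon_starts, paste, character(1),
                         collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, character(1),
                       collapse = ","),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$tx_start), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
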