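#' Generate a random genome at a target GC content
#'
#' Chromosomes are i.i.d. base strings named chr1, chr2, ...; the same
#' configuration (including its seed) always reproduces the same
#' sequences.
#'
#' @param config a [synth_config()].
#' @return named character vector of chromosome sequences.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$chrom_length <= 0) stop("chromosome length must be positive")
  gc <- config$gc_content
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed_if(derive_seed(config$seed, "genome"), {
    setNames(
      vapply(seq_len(config$n_chromosomes), function(i) {
        paste(sample(BASES, config$chrom_length, replace = TRUE, prob = p),
              collapse = "")
      }, character(1)),
      paste0("chr", seq_len(config$n_chromosomes))
    )
  })
}

## Validate a gene-model data.frame and attach TSS/TES columns.
## TSS = start for "+" genes, end - 1 for "-" genes (0-based base of the
## first transcribed position); TES is the opposite end.
finalize_genes <- function(df) {
  stopifnot(all(df$strand %in% c("+", "-")))
  if (any(df$end <= df$start)) stop("gene end <= start")
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) < 1) stop("gene ", df$gene_id[i], " has no exons")
    if (any(es < df$start[i]) || any(ee > df$end[i])) {
      stop("gene ", df$gene_id[i], ": exon outside transcript bounds")
    }
    if (any(ee <= es)) stop("gene ", df$gene_id[i], ": empty exon")
    if (!is.na(df$cds_start[i]) &&
        (df$cds_start[i] < df$start[i] || df$cds_end[i] > df$end[i])) {
      stop("gene ", df$gene_id[i], ": CDS outside transcript bounds")
    }
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tes <- ifelse(df$strand == "+", df$end - 1, df$start)
  df
}

#' Generate stranded gene models on a genome
#'
#' Genes are placed without overlap, separated by at least 15 kb so that
#' promoter/TES windows of neighbours only occasionally collide.
#' Transcripts are ~24-36 kb with 4-8 exons covering ~55-65% of the
#' body and a CDS spanning the central half of the exonic bases; about
#' half the genes fall on each strand. This compact architecture is
#' chosen to give a roughly balanced per-base feature-category
#' composition on the small synthetic genome, not to mimic genome-wide
#' human gene statistics.
#'
#' @param genome named character vector of sequences, or named numeric
#'   chromosome lengths when no sequence is needed.
#' @param config a [synth_config()].
#' @return gene-model data.frame with columns gene_id, chrom, start,
#'   end, strand, cds_start, cds_end, list-columns exon_starts /
#'   exon_ends, and derived tss / tes (all 0-based half-open).
#' @export
generate_gene_models <- function(genome, config) {
  stopifnot(inherits(config, "synth_config"))
  lens <- chrom_lengths(genome)
  if (!length(lens)) stop("genome is empty")
  n <- config$n_genes
  min_gap <- 15000
  tx_min <- 24000; tx_max <- 36000
  per <- apportion(n, lens / sum(lens))
  capacity <- floor((lens - min_gap) / (tx_max + min_gap))
  if (any(per > capacity)) {
    stop("n_genes = ", n, " exceeds placeable capacity (",
         sum(capacity), " genes at current chromosome lengths)")
  }
  with_seed_if(derive_seed(config$seed, "genes"), {
    rows <- list()
    gid <- 0L
    for (ci in seq_along(lens)) {
      k <- per[ci]
      if (k == 0) next
      L <- lens[ci]
      tx <- round(runif(k, tx_min, tx_max))
      ## stick-breaking for the k+1 gaps, each at least min_gap
      free <- L - sum(tx) - (k + 1) * min_gap
      w <- rexp(k + 1)
      gaps <- min_gap + floor(free * w / sum(w))
      starts <- cumsum(c(gaps[1], tx[-k] + gaps[2:k]))
      if (k == 1) starts <- gaps[1]
      for (j in seq_len(k)) {
        gid <- gid + 1L
        s <- starts[j]; e <- s + tx[j]
        n_ex <- sample(4:8, 1)
        exonic <- round(tx[j] * runif(1, 0.55, 0.65))
        ex_len <- pmax(200, floor(exonic * prop_table(n_ex)))
        in_len <- pmax(200, floor((tx[j] - sum(ex_len)) *
                                    prop_table(n_ex - 1)))
        ## lay out exon1 intron1 exon2 ... exonN, then clamp to tx end
        es <- numeric(n_ex); ee <- numeric(n_ex)
        pos <- s
        for (x in seq_len(n_ex)) {
          es[x] <- pos; ee[x] <- pos + ex_len[x]
          pos <- ee[x] + if (x < n_ex) in_len[x] else 0
        }
        if (ee[n_ex] > e) {
          shrink <- ee[n_ex] - e
          ee[n_ex] <- ee[n_ex] - shrink
          if (ee[n_ex] - es[n_ex] < 100) { es[n_ex] <- ee[n_ex] - 100 }
        } else {
          ee[n_ex] <- e  # last exon runs to the transcript end
        }
        ## CDS covers the central half of exonic bases
        exonic_tot <- sum(ee - es)
        cds_lo <- exonic_base_to_genomic(es, ee, round(exonic_tot * 0.25))
        cds_hi <- exonic_base_to_genomic(es, ee, round(exonic_tot * 0.75))
        rows[[gid]] <- list(gene_id = sprintf("gene%04d", gid),
                            chrom = names(lens)[ci], start = s, end = e,
                            strand = sample(c("+", "-"), 1),
                            cds_start = cds_lo, cds_end = cds_hi,
                            exon_starts = es, exon_ends = ee)
      }
    }
    df <- data.frame(
      gene_id = vapply(rows, `[[`, character(1), "gene_id"),
      chrom = vapply(rows, `[[`, character(1), "chrom"),
      start = vapply(rows, `[[`, numeric(1), "start"),
      end = vapply(rows, `[[`, numeric(1), "end"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      cds_start = vapply(rows, `[[`, numeric(1), "cds_start"),
      cds_end = vapply(rows, `[[`, numeric(1), "cds_end"),
      stringsAsFactors = FALSE
    )
    df$exon_starts <- I(lapply(rows, `[[`, "exon_starts"))
    df$exon_ends <- I(lapply(rows, `[[`, "exon_ends"))
    finalize_genes(df)
  })
}

## Random proportions (Dirichlet(2)) for splitting a span into k parts.
prop_table <- function(k) {
  if (k <= 0) return(numeric(0))
  g <- rgamma(k, shape = 2)
  g / sum(g)
}

## Genomic coordinate of the n-th exonic base (0-based within exons).
exonic_base_to_genomic <- function(es, ee, n) {
  widths <- ee - es
  cw <- cumsum(widths)
  i <- which(cw > n)[1]
  prev <- if (i > 1) cw[i - 1] else 0
  es[i] + (n - prev)
}
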