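#' Split genes into expression strata (top 30 / middle 40 / bottom 30)
#'
#' Genes are ranked by expression, descending; the top ceiling(f1 * n)
#' form the high group, the next ceiling(f2 * n) the middle group, and
#' the remainder the low group. Ties are broken by gene id
#' (lexicographic) for determinism.
#'
#' @param expression data.frame (gene_id, expr).
#' @param fractions length-3 fractions summing to 1.
#' @return named list of gene-id vectors: top30, middle40, bottom30.
#' @export
tertile_split <- function(expression, fractions = c(0.30, 0.40, 0.30)) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  stop_if_not_df(expression, c("gene_id", "expr"), "expression")
  if (anyNA(expression$expr)) stop("expression values missing")
  o <- order(-expression$expr, expression$gene_id)
  ids <- expression$gene_id[o]
  n <- length(ids)
  n1 <- ceiling(fractions[1] * n)
  n2 <- min(ceiling(fractions[2] * n), n - n1)
  list(top30 = ids[seq_len(n1)],
       middle40 = ids[n1 + seq_len(n2)],
       bottom30 = if (n1 + n2 < n) ids[(n1 + n2 + 1):n] else character(0))
}

#' TSS-anchored metaprofile of peak midpoints for a gene group
#'
#' For every (peak, gene) pair whose peak midpoint falls within
#' [-window, window) of the gene's TSS, the signed strand-oriented
#' offset is histogrammed into fixed bins; a peak near two genes
#' contributes one event to each. Density is counts divided by the
#' group's gene count.
#'
#' @param peaks peak data.frame (chrom, start, end).
#' @param genes gene-model data.frame.
#' @param gene_ids gene ids forming the group (NULL: all genes).
#' @param window profile half-width (bp).
#' @param bin bin width (bp); must divide 2 * window.
#' @param group label stored in the output.
#' @return data.frame (group, bin_start, bin_end, count, density) with
#'   TSS-oriented bin edges from -window to window.
#' @export
tss_metaprofile <- function(peaks, genes, gene_ids = NULL, window = 10000,
                            bin = 200, group = "all") {
  if ((2 * window) %% bin != 0) stop("bin must divide 2 * window")
  g <- if (is.null(gene_ids)) genes else
    genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  edges <- seq(-window, window, by = bin)
  counts <- integer(length(edges) - 1)
  if (nrow(g) && nrow(peaks)) {
    mids <- peak_midpoints(peaks)
    for (ch in unique(g$chrom)) {
      gi <- which(g$chrom == ch)
      pi <- which(peaks$chrom == ch)
      if (!length(pi)) next
      win <- to_iranges(g$tss[gi] - window, g$tss[gi] + window)
      pts <- to_iranges(mids[pi], mids[pi] + 1)
      ov <- IRanges::findOverlaps(pts, win)
      if (!length(ov)) next
      p <- pi[S4Vectors::queryHits(ov)]
      gg <- gi[S4Vectors::subjectHits(ov)]
      off <- ifelse(g$strand[gg] == "+", mids[p] - g$tss[gg],
                    g$tss[gg] - mids[p])
      keep <- off >= -window & off < window
      counts <- counts + tabulate(floor((off[keep] + window) / bin) + 1L,
                                  nbins = length(counts))
    }
  }
  data.frame(group = group, bin_start = edges[-length(edges)],
             bin_end = edges[-1], count = counts,
             density = if (nrow(g)) counts / nrow(g) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Intersect peak-linked genes with differential-expression calls
#'
#' @param links peak-gene link table from [map_peaks_to_genes()].
#' @param expression data.frame (gene_id, fold_change), signed linear
#'   fold changes.
#' @param fc_threshold symmetric threshold; up = fold change >
#'   `fc_threshold`, down = fold change < `-fc_threshold`.
#' @return list with `up` and `down` gene-id vectors (each gene counted
#'   once regardless of peak multiplicity).
#' @export
intersect_de_genes <- function(links, expression, fc_threshold = 1.5) {
  stop_if_not_df(expression, c("gene_id", "fold_change"), "expression")
  genes <- unique(links$gene_id)
  fc <- expression$fold_change[match(genes, expression$gene_id)]
  if (anyNA(fc)) {
    warning(sum(is.na(fc)), " linked gene(s) missing a fold change; skipped")
    genes <- genes[!is.na(fc)]
    fc <- fc[!is.na(fc)]
  }
  list(up = sort(genes[fc > fc_threshold]),
       down = sort(genes[fc < -fc_threshold]))
}

#' DNase-hypersensitivity co-occurrence with peaks
#'
#' A peak is flagged when any DHS interval overlaps
#' [peak.start - margin, peak.end + margin) (0-based half-open).
#'
#' @param peaks peak data.frame (chrom, start, end).
#' @param dhs DHS interval data.frame (chrom, start, end).
#' @param margin flanking margin in bp.
#' @return list with `fraction` (flagged peaks / total) and per-peak
#'   logical `flags`.
#' @export
dhs_cooccurrence <- function(peaks, dhs, margin = 1000) {
  if (margin < 0) stop("margin must be >= 0")
  stop_if_not_df(peaks, c("chrom", "start", "end"), "peaks")
  flags <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    di <- which(dhs$chrom == ch)
    if (!length(di)) next
    win <- to_iranges(pmax(peaks$start[pi] - margin, 0),
                      peaks$end[pi] + margin)
    flags[pi] <- IRanges::overlapsAny(win, to_iranges(dhs$start[di],
                                                      dhs$end[di]))
  }
  list(fraction = if (nrow(peaks)) mean(flags) else NA_real_,
       flags = flags)
}
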