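#' Feature-category vocabulary
#'
#' Categories, in decreasing precedence: promoter (within the promoter
#' window strictly upstream of a TSS, strand-oriented), tes (within the
#' TES window downstream of a transcription end site), coding (inside a
#' CDS), exon (inside a non-CDS exon), intron (inside a gene body but no
#' exon), intergenic (none of the above).
#'
#' @export
FEATURE_CATEGORIES <- c("promoter", "tes", "coding", "exon", "intron",
                        "intergenic")

#' Per-base feature-category masks under precedence
#'
#' Builds, per chromosome, disjoint interval sets labelling every base
#' with exactly one feature category. The same masks drive both
#' [assign_category()] and the synthetic generator's category-targeted
#' peak placement, so planted truth labels are recovered exactly.
#'
#' @param genes gene-model data.frame.
#' @param lengths named chromosome lengths.
#' @param promoter_window bp upstream of TSS counted as promoter.
#' @param tes_window bp downstream of TES counted as tes.
#' @param precedence category order, highest first.
#' @return named list (per chromosome) of named lists of
#'   [IRanges::IRanges] objects, one per category.
#' @export
category_masks <- function(genes, lengths, promoter_window = 10000,
                           tes_window = 10000,
                           precedence = FEATURE_CATEGORIES) {
  stopifnot(setequal(precedence, FEATURE_CATEGORIES))
  out <- list()
  for (ch in names(lengths)) {
    L <- lengths[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ir0 <- IRanges::IRanges()
    clip <- function(s, e) {
      s <- pmax(s, 0); e <- pmin(e, L)
      keep <- e > s
      IRanges::reduce(to_iranges(s[keep], e[keep]))
    }
    raw <- list()
    if (nrow(g)) {
      plus <- g$strand == "+"
      raw$promoter <- clip(ifelse(plus, g$start - promoter_window, g$end),
                           ifelse(plus, g$start, g$end + promoter_window))
      ## downstream window includes the TES base itself
      raw$tes <- clip(ifelse(plus, g$end - 1, g$start - tes_window + 1),
                      ifelse(plus, g$end - 1 + tes_window, g$start + 1))
      has_cds <- !is.na(g$cds_start)
      es <- unlist(g$exon_starts); ee <- unlist(g$exon_ends)
      ## coding = exonic bases inside the CDS span (CDS introns excluded)
      raw$coding <- IRanges::intersect(
        clip(g$cds_start[has_cds], g$cds_end[has_cds]), clip(es, ee))
      raw$exon <- clip(es, ee)
      raw$intron <- clip(g$start, g$end)  # gene bodies; exons removed below
    } else {
      raw <- list(promoter = ir0, tes = ir0, coding = ir0, exon = ir0,
                  intron = ir0)
    }
    ## structural containment first: exon excludes CDS, intron excludes exons
    raw$intron <- IRanges::setdiff(raw$intron,
                                   IRanges::union(raw$exon, raw$coding))
    raw$exon <- IRanges::setdiff(raw$exon, raw$coding)
    raw$intergenic <- to_iranges(0, L)
    masks <- list()
    taken <- ir0
    for (cat in precedence) {
      m <- IRanges::setdiff(raw[[cat]], taken)
      masks[[cat]] <- m
      taken <- IRanges::union(taken, m)
    }
    out[[ch]] <- masks
  }
  out
}

peak_midpoints <- function(peaks) floor((peaks$start + peaks$end) / 2)

#' Assign each peak to a feature category
#'
#' The decision is made at the peak midpoint with precedence
#' promoter > tes > coding > exon > intron > intergenic (configurable).
#'
#' @param peaks data.frame with chrom, start, end (0-based half-open).
#' @param genes gene-model data.frame.
#' @param lengths named chromosome lengths; inferred from peak/gene
#'   extents when NULL.
#' @param promoter_window,tes_window window sizes in bp.
#' @param precedence category order, highest first.
#' @return factor of categories, one per peak.
#' @export
assign_category <- function(peaks, genes, lengths = NULL,
                            promoter_window = 10000, tes_window = 10000,
                            precedence = FEATURE_CATEGORIES) {
  stop_if_not_df(peaks, c("chrom", "start", "end"), "peaks")
  if (is.null(lengths)) {
    chs <- unique(c(peaks$chrom, genes$chrom))
    lengths <- setNames(vapply(chs, function(ch) {
      max(peaks$end[peaks$chrom == ch], genes$end[genes$chrom == ch],
          0) + promoter_window + tes_window
    }, numeric(1)), chs)
  }
  masks <- category_masks(genes, lengths, promoter_window, tes_window,
                          precedence)
  mids <- peak_midpoints(peaks)
  res <- rep(NA_character_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    pts <- to_iranges(mids[sel], mids[sel] + 1)
    for (cat in precedence) {
      m <- masks[[ch]][[cat]]
      if (is.null(m) || !length(m)) next
      hit <- IRanges::overlapsAny(pts, m)
      res[sel][hit & is.na(res[sel])] <- cat
    }
    res[sel][is.na(res[sel])] <- "intergenic"
  }
  factor(res, levels = FEATURE_CATEGORIES)
}

#' Summarize peak feature categories as percentages
#'
#' @inheritParams assign_category
#' @param ... passed to [assign_category()].
#' @return data.frame (category, count, percent); percentages sum to 100
#'   up to rounding.
#' @export
summarize_categories <- function(peaks, genes, ...) {
  if (!nrow(peaks)) stop("empty peak list")
  cats <- assign_category(peaks, genes, ...)
  tab <- table(cats)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(peaks),
             stringsAsFactors = FALSE)
}

#' Map peaks to genes within a TSS window
#'
#' A link is created when the peak midpoint lies within `window` bp of a
#' gene's TSS on either side; the offset is signed in gene orientation
#' (negative = upstream). A peak may link to several genes and a gene to
#' several peaks.
#'
#' @param peaks peak data.frame (needs chrom, start, end; a `peak_id`
#'   column is used when present).
#' @param genes gene-model data.frame.
#' @param window half-width of the TSS window in bp (closed at both
#'   ends).
#' @return list with `links` (peak_id, gene_id, offset), `n_peaks`
#'   (distinct peaks linked) and `n_genes` (distinct genes linked).
#' @export
map_peaks_to_genes <- function(peaks, genes, window = 10000) {
  if (window <= 0) stop("window must be positive")
  stop_if_not_df(peaks, c("chrom", "start", "end"), "peaks")
  ids <- if ("peak_id" %in% names(peaks)) peaks$peak_id else
    sprintf("peak%05d", seq_len(nrow(peaks)))
  mids <- peak_midpoints(peaks)
  links <- list()
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(pi) || !length(gi)) next
    win <- to_iranges(genes$tss[gi] - window, genes$tss[gi] + window + 1)
    pts <- to_iranges(mids[pi], mids[pi] + 1)
    ov <- IRanges::findOverlaps(pts, win)
    if (!length(ov)) next
    p <- pi[S4Vectors::queryHits(ov)]
    g <- gi[S4Vectors::subjectHits(ov)]
    off <- ifelse(genes$strand[g] == "+", mids[p] - genes$tss[g],
                  genes$tss[g] - mids[p])
    links[[ch]] <- data.frame(peak_id = ids[p], gene_id = genes$gene_id[g],
                              offset = off, stringsAsFactors = FALSE)
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(peak_id = character(0), gene_id = character(0),
               offset = numeric(0), stringsAsFactors = FALSE)
  links <- links[order(links$peak_id, links$gene_id), , drop = FALSE]
  rownames(links) <- NULL
  list(links = links, n_peaks = length(unique(links$peak_id)),
       n_genes = length(unique(links$gene_id)))
}

#' Binned peak-density track
#'
#' Tiles each chromosome with fixed bins, counts peak midpoints per bin
#' and reports log2(count + 1).
#'
#' @param peaks peak data.frame.
#' @param lengths named chromosome lengths.
#' @param bin bin width in bp.
#' @return data.frame (chrom, bin_start, bin_end, count, log2_density).
#' @export
density_track <- function(peaks, lengths, bin = 1e6) {
  if (bin <= 0) stop("bin must be positive")
  mids <- peak_midpoints(peaks)
  out <- lapply(names(lengths), function(ch) {
    edges <- seq(0, ceiling(lengths[[ch]] / bin) * bin, by = bin)
    m <- mids[peaks$chrom == ch]
    counts <- as.integer(table(cut(m, edges, right = FALSE,
                                   include.lowest = FALSE)))
    data.frame(chrom = ch, bin_start = edges[-length(edges)],
               bin_end = pmin(edges[-1], lengths[[ch]]), count = counts,
               log2_density = log2(counts + 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between binned gene and peak densities
#'
#' Pearson correlation between per-bin gene counts (by gene midpoint)
#' and per-bin peak counts (by peak midpoint) across the genome.
#'
#' @param peaks peak data.frame.
#' @param genes gene-model data.frame.
#' @param lengths named chromosome lengths.
#' @param bin bin width in bp.
#' @return correlation coefficient, or NA (with a warning) when either
#'   binned vector has zero variance.
#' @export
gene_peak_density_correlation <- function(peaks, genes, lengths,
                                          bin = 1e6) {
  if (bin <= 0) stop("bin must be positive")
  pk <- density_track(peaks, lengths, bin)
  gn <- density_track(data.frame(chrom = genes$chrom, start = genes$start,
                                 end = genes$end), lengths, bin)
  if (nrow(pk) < 2) stop("need at least 2 bins")
  if (sd(pk$count) == 0 || sd(gn$count) == 0) {
    warning("zero-variance density vector; correlation undefined")
    return(NA_real_)
  }
  cor(pk$count, gn$count)
}
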