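## Interval I/O. All internal coordinates are 0-based half-open
## (BED-like); conversions to and from 1-based inclusive conventions
## (GFF, IRanges) happen here and nowhere else.

new_intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                          score = NA_real_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = name, score = score,
                   strand = strand, stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("interval end <= start at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  df
}

sort_intervals <- function(df) df[order(df$chrom, df$start, df$end), , drop = FALSE]

#' Read a BED file (3-6 columns) as 0-based half-open intervals
#'
#' A light validation pass reports malformed lines (too few fields,
#' non-numeric or inverted coordinates, unknown strand symbols) with
#' their line numbers before the file is parsed by rtracklayer.
#'
#' @param path path to a BED file.
#' @return data.frame with columns chrom, start, end, name, score, strand
#'   (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("BED line ", i, ": non-numeric coordinates")
    if (e <= s) stop("BED line ", i, ": end <= start")
    if (length(f) >= 6 && !f[6] %in% c("+", "-", ".")) {
      stop("BED line ", i, ": unknown strand symbol '", f[6], "'")
    }
  }
  gr <- rtracklayer::import(path, format = "bed")
  new_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = {
      s <- as.character(GenomicRanges::strand(gr)); s[s == "*"] <- "."; s
    },
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  )
}

#' Write 0-based half-open intervals as BED
#'
#' Output is sorted chromosome-lexicographically, then by start.
#'
#' @param intervals data.frame with chrom, start, end and optionally
#'   name, score, strand columns (0-based half-open).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stop_if_not_df(intervals, c("chrom", "start", "end"), "intervals")
  df <- sort_intervals(intervals)
  n <- nrow(df)
  name <- if ("name" %in% names(df)) as.character(df$name) else rep(NA, n)
  score <- if ("score" %in% names(df)) df$score else rep(NA, n)
  strand <- if ("strand" %in% names(df)) as.character(df$strand) else rep(".", n)
  name[is.na(name)] <- "."
  score_chr <- ifelse(is.na(score), "0", format(score, trim = TRUE, scientific = FALSE))
  strand[is.na(strand)] <- "."
  out <- paste(df$chrom, format(df$start, trim = TRUE, scientific = FALSE),
               format(df$end, trim = TRUE, scientific = FALSE),
               name, score_chr, strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene` features carrying an `ID` attribute with child `exon`
#' and `CDS` features pointing at the gene via `Parent`. GFF's 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention at this boundary.
#'
#' @param path path to a GFF3 file.
#' @return a gene-model data.frame (see [generate_gene_models()] for the
#'   column contract).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  gi <- which(type == "gene")
  if (!length(gi)) stop("no 'gene' features in ", path)
  ids <- as.character(gr$ID[gi])
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  genes <- lapply(seq_along(gi), function(k) {
    i <- gi[k]
    id <- ids[k]
    ex <- which(type == "exon" & parent == id)
    cds <- which(type == "CDS" & parent == id)
    list(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      start = GenomicRanges::start(gr)[i] - 1L,
      end = GenomicRanges::end(gr)[i],
      strand = as.character(GenomicRanges::strand(gr)[i]),
      exon_starts = GenomicRanges::start(gr)[ex] - 1L,
      exon_ends = GenomicRanges::end(gr)[ex],
      cds_start = if (length(cds)) min(GenomicRanges::start(gr)[cds]) - 1L else NA_real_,
      cds_end = if (length(cds)) max(GenomicRanges::end(gr)[cds]) else NA_real_
    )
  })
  df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = vapply(genes, function(g) as.numeric(g$start), numeric(1)),
    end = vapply(genes, function(g) as.numeric(g$end), numeric(1)),
    strand = vapply(genes, `[[`, character(1), "strand"),
    cds_start = vapply(genes, function(g) as.numeric(g$cds_start), numeric(1)),
    cds_end = vapply(genes, function(g) as.numeric(g$cds_end), numeric(1)),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- I(lapply(genes, function(g) {
    o <- order(g$exon_starts); as.numeric(g$exon_starts[o])
  }))
  df$exon_ends <- I(lapply(genes, function(g) {
    o <- order(g$exon_starts); as.numeric(g$exon_ends[o])
  }))
  finalize_genes(df)
}

#' Write gene models as GFF3
#'
#' @param genes gene-model data.frame (0-based half-open internally;
#'   written 1-based inclusive).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff_genes <- function(genes, path) {
  stop_if_not_df(genes, c("gene_id", "chrom", "start", "end", "strand"),
                 "genes")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rows <- character(0)
  gff_row <- function(chrom, type, s0, e0, strand, attrs) {
    paste(chrom, "tilechip", type, s0 + 1, e0, ".", strand, ".", attrs,
          sep = "\t")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    id <- g$gene_id
    rows <- c(rows, gff_row(g$chrom, "gene", g$start, g$end, g$strand,
                            paste0("ID=", id)))
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    for (j in seq_along(es)) {
      rows <- c(rows, gff_row(g$chrom, "exon", es[j], ee[j], g$strand,
                              paste0("ID=", id, ".exon", j, ";Parent=", id)))
    }
    if (!is.na(g$cds_start)) {
      cs <- pmax(es, g$cds_start); ce <- pmin(ee, g$cds_end)
      k <- which(cs < ce)
      for (j in seq_along(k)) {
        rows <- c(rows, gff_row(g$chrom, "CDS", cs[k[j]], ce[k[j]], g$strand,
                                paste0("ID=", id, ".cds", j, ";Parent=", id)))
      }
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a WIG file (fixedStep or variableStep) as a probe track
#'
#' Positions in WIG are 1-based; they are converted to the internal
#' 0-based convention. Malformed declaration or data lines are reported
#' with their line numbers.
#'
#' @param path path to a WIG file.
#' @return probe-track data.frame with columns chrom, start, ratio.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  chrom <- NULL; mode <- NULL; pos <- NA; step <- NA; span <- 1
  out_chrom <- character(0); out_start <- numeric(0); out_val <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(track|#)", ln)) next
    if (grepl("^fixedStep", ln) || grepl("^variableStep", ln)) {
      kv <- regmatches(ln, gregexpr("[A-Za-z]+=[^ \t]+", ln))[[1]]
      kvs <- strsplit(kv, "=", fixed = TRUE)
      keys <- vapply(kvs, `[`, character(1), 1)
      vals <- vapply(kvs, `[`, character(1), 2)
      named <- setNames(vals, keys)
      if (!"chrom" %in% keys) stop("WIG line ", i, ": missing chrom=")
      chrom <- named[["chrom"]]
      mode <- if (grepl("^fixedStep", ln)) "fixed" else "variable"
      span <- if ("span" %in% keys) as.numeric(named[["span"]]) else 1
      if (mode == "fixed") {
        if (!all(c("start", "step") %in% keys)) {
          stop("WIG line ", i, ": fixedStep requires start= and step=")
        }
        pos <- as.numeric(named[["start"]])
        step <- as.numeric(named[["step"]])
      }
      next
    }
    if (is.null(mode)) stop("WIG line ", i, ": data before any declaration")
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (mode == "fixed") {
      v <- suppressWarnings(as.numeric(f[1]))
      if (is.na(v)) stop("WIG line ", i, ": non-numeric value")
      out_chrom <- c(out_chrom, chrom); out_start <- c(out_start, pos - 1)
      out_val <- c(out_val, v)
      pos <- pos + step
    } else {
      if (length(f) < 2) stop("WIG line ", i, ": variableStep needs pos value")
      p <- suppressWarnings(as.numeric(f[1]))
      v <- suppressWarnings(as.numeric(f[2]))
      if (is.na(p) || is.na(v)) stop("WIG line ", i, ": non-numeric fields")
      out_chrom <- c(out_chrom, chrom); out_start <- c(out_start, p - 1)
      out_val <- c(out_val, v)
    }
  }
  if (!length(out_val)) stop("empty WIG file: ", path)
  df <- data.frame(chrom = out_chrom, start = out_start, ratio = out_val,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write a probe track as fixedStep WIG
#'
#' Requires constant probe spacing per chromosome (the tiling-array
#' layout); chromosomes are emitted in lexicographic order.
#'
#' @param track probe-track data.frame (chrom, start, ratio).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_wig <- function(track, path) {
  stop_if_not_df(track, c("chrom", "start", "ratio"), "track")
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in sort(unique(track$chrom))) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    steps <- unique(diff(sub$start))
    if (nrow(sub) > 1 && length(steps) != 1) {
      stop("write_wig needs constant probe spacing on ", ch,
           "; use write_probe_tsv for irregular tracks")
    }
    step <- if (nrow(sub) > 1) steps else 1
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d", ch,
                       as.integer(sub$start[1] + 1), as.integer(step)), con)
    writeLines(format(sub$ratio, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}

#' Read / write a probe table as TSV
#'
#' Columns: chrom, probe_start (0-based), log2_ratio.
#'
#' @param path file path.
#' @return `read_probe_tsv`: probe-track data.frame (chrom, start, ratio).
#' @export
read_probe_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "probe_start", "log2_ratio")
  if (!all(need %in% names(df))) {
    stop("probe TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(chrom = as.character(df$chrom),
                    start = as.numeric(df$probe_start),
                    ratio = as.numeric(df$log2_ratio),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname read_probe_tsv
#' @param track probe-track data.frame (chrom, start, ratio).
#' @export
write_probe_tsv <- function(track, path) {
  stop_if_not_df(track, c("chrom", "start", "ratio"), "track")
  df <- track[order(track$chrom, track$start), , drop = FALSE]
  out <- data.frame(chrom = df$chrom, probe_start = df$start,
                    log2_ratio = df$ratio)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression table as TSV
#'
#' Columns: gene_id, expr (expression level) and fold_change (signed
#' linear fold change; `log2fc` is accepted as an alias on read).
#'
#' @param path file path.
#' @return `read_expression_tsv`: data.frame (gene_id, expr, fold_change).
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("log2fc" %in% names(df) && !"fold_change" %in% names(df)) {
    names(df)[names(df) == "log2fc"] <- "fold_change"
  }
  need <- c("gene_id", "expr", "fold_change")
  if (!all(need %in% names(df))) {
    stop("expression TSV must have columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' @rdname read_expression_tsv
#' @param expression data.frame (gene_id, expr, fold_change).
#' @export
write_expression_tsv <- function(expression, path) {
  stop_if_not_df(expression, c("gene_id", "expr", "fold_change"),
                 "expression")
  write.table(expression[, c("gene_id", "expr", "fold_change")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
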