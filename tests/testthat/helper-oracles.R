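## Shared fixtures and independent oracle implementations.

mk_track <- function(ratios, spacing = 100, chrom = "chr1", start0 = 0) {
  if (!length(ratios)) chrom <- character(0)
  tr <- data.frame(chrom = chrom,
                   start = start0 + spacing * (seq_along(ratios) - 1),
                   ratio = ratios, stringsAsFactors = FALSE)
  attr(tr, "spacing") <- spacing
  tr
}

## Minimal gene-model builder (0-based half-open, one exon by default).
mk_gene <- function(gene_id, chrom, start, end, strand = "+",
                    exon_starts = list(start), exon_ends = list(end),
                    cds_start = NA, cds_end = NA) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                   end = end, strand = strand, cds_start = cds_start,
                   cds_end = cds_end, stringsAsFactors = FALSE)
  df$exon_starts <- I(list(unlist(exon_starts)))
  df$exon_ends <- I(list(unlist(exon_ends)))
  df$tss <- if (strand == "+") start else end - 1
  df$tes <- if (strand == "+") end - 1 else start
  df
}

mk_genes <- function(...) {
  do.call(rbind, list(...))
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

## ---- peak-caller oracles (independent routes) -----------------------

## Brute-force qualified regions at one cutoff: enumerate clusters and
## test qualification by explicit window / run enumeration.
oracle_regions <- function(pos, ratio, cutoff, window = 500,
                           min_probes = 4, min_all = 2) {
  ab <- which(ratio > cutoff)
  if (!length(ab)) return(NULL)
  grp <- cumsum(c(1, diff(pos[ab]) > window))
  out <- NULL
  for (g in unique(grp)) {
    members <- ab[grp == g]
    a <- pos[members]
    ok <- FALSE
    ## any window of `window` bp holding >= min_probes above probes:
    ## anchor a window at every above-probe position
    for (x in a) {
      if (sum(a >= x & a < x + window) >= min_probes) { ok <- TRUE; break }
    }
    if (!ok && min_all >= 1) {
      ## explicit run scan over track indices
      for (i in seq_along(members)) {
        run <- 1
        j <- i
        while (j < length(members) && members[j + 1] == members[j] + 1) {
          run <- run + 1
          j <- j + 1
        }
        if (run >= min_all) { ok <- TRUE; break }
      }
    }
    if (ok) out <- rbind(out, c(min(a), max(a)))
  }
  out
}

## Independent full caller: per-probe score painting, peaks from
## contiguous painted probes (valid for constant-spacing tracks).
oracle_call_peaks <- function(track, params) {
  res <- NULL
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    pos <- sub$start; r <- sub$ratio
    sp <- attr(track, "spacing")
    hyp <- mean(r) + params$hypmax_k * sqrt(mean((r - mean(r))^2))
    pct <- params$p_start - params$p_step * (seq_len(params$n_steps) - 1)
    paint <- rep(0, length(pos))
    for (s in pct) {
      m <- oracle_regions(pos, r, s / 100 * hyp, params$window,
                          params$min_probes, params$min_probes_all_above)
      if (is.null(m)) next
      for (k in seq_len(nrow(m))) {
        sel <- pos >= m[k, 1] & pos < m[k, 2] + sp
        paint[sel] <- pmax(paint[sel], s)
      }
    }
    rl <- rle(paint > 0)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in which(rl$values)) {
      i <- starts[k]:ends[k]
      res <- rbind(res, data.frame(chrom = ch, start = pos[i[1]],
                                   end = pos[i[length(i)]] + sp,
                                   score = max(paint[i]),
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(res)) return(res)
  res[order(res$chrom, res$start), ]
}

## ---- annotation oracle ----------------------------------------------

oracle_links <- function(peaks, genes, window = 10000) {
  out <- NULL
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      off <- if (genes$strand[j] == "+") mid - genes$tss[j] else
        genes$tss[j] - mid
      if (abs(off) <= window) {
        out <- rbind(out, data.frame(peak_id = peaks$peak_id[i],
                                     gene_id = genes$gene_id[j],
                                     offset = off,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

## ---- match-score oracle (direct formula recomputation) --------------

oracle_match_score <- function(x, window) {
  f <- sweep(x$counts, 2, colSums(x$counts), "/")
  Iw <- vapply(seq_len(ncol(f)), function(i) {
    fi <- f[, i]
    sum(ifelse(fi > 0, fi * log(4 * fi), 0))
  }, numeric(1))
  b <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  cur <- sum(Iw * f[cbind(b, seq_len(ncol(f)))])
  lo <- sum(Iw * apply(f, 2, min))
  hi <- sum(Iw * apply(f, 2, max))
  (cur - lo) / (hi - lo)
}

## ---- regex consensus oracle (overlapping matches via lookahead) -----

oracle_consensus_counts <- function(sequences, pattern_string,
                                    revcomp_too = TRUE) {
  count_one <- function(s, p) {
    m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  ## reverse complement of a bracket pattern: complement sets, reverse
  rc_pattern <- function(p) {
    toks <- regmatches(p, gregexpr("\\[[A-Z]+\\]|[A-Z]", p))[[1]]
    comp <- function(tok) {
      ltrs <- gsub("\\[|\\]", "", tok)
      cs <- chartr("ACGT", "TGCA", ltrs)
      if (nchar(cs) > 1) paste0("[", cs, "]") else cs
    }
    paste(rev(vapply(toks, comp, character(1))), collapse = "")
  }
  vapply(sequences, function(s) {
    n <- count_one(s, pattern_string)
    if (revcomp_too) n <- n + count_one(s, rc_pattern(pattern_string))
    n
  }, integer(1), USE.NAMES = FALSE)
}

## orientation-agnostic mean per-column correlation of two pwms
pwm_column_cor <- function(a, b) {
  qa <- tilechip:::pwm_freq(a); qb <- tilechip:::pwm_freq(b)
  fwd <- mean(vapply(seq_len(ncol(qa)),
                     function(j) cor(qa[, j], qb[, j]), numeric(1)))
  qr <- qa[4:1, ncol(qa):1]
  rc <- mean(vapply(seq_len(ncol(qa)),
                    function(j) cor(qr[, j], qb[, j]), numeric(1)))
  max(fwd, rc)
}

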