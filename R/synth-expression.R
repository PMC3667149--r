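#' Simulate expression levels and MOF-knockdown-style differential calls
#'
#' Expression levels are log-normal (heavy-tailed, effectively always
#' distinct, so rank splits are unambiguous). `de_up` genes receive a
#' signed fold change above +1.5, `de_down` genes below -1.5, and the
#' remainder fall in (-1.5, 1.5) with magnitude >= 1 (the natural range
#' of a signed linear fold change).
#'
#' @param genes gene-model data.frame.
#' @param config a [synth_config()].
#' @return data.frame (gene_id, expr, fold_change, de) where `de` is
#'   one of "up", "down", "null".
#' @export
simulate_expression_and_de <- function(genes, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(genes)
  if (!n) stop("no genes")
  if (config$de_up + config$de_down > n) {
    stop("de_up + de_down exceeds number of genes")
  }
  with_seed_if(derive_seed(config$seed, "expression"), {
    expr <- rlnorm(n, meanlog = 5, sdlog = 1.5)
    de <- rep("null", n)
    pick <- sample.int(n, config$de_up + config$de_down)
    de[pick[seq_len(config$de_up)]] <- "up"
    if (config$de_down > 0) {
      de[pick[config$de_up + seq_len(config$de_down)]] <- "down"
    }
    fc <- numeric(n)
    is_null <- de == "null"
    fc[is_null] <- sample(c(-1, 1), sum(is_null), replace = TRUE) *
      pmin(1 + abs(rnorm(sum(is_null), 0, 0.2)), 1.499)
    fc[de == "up"] <- 1.5 + rexp(config$de_up, rate = 2)
    fc[de == "down"] <- -(1.5 + rexp(config$de_down, rate = 2))
    data.frame(gene_id = genes$gene_id, expr = expr, fold_change = fc,
               de = de, stringsAsFactors = FALSE)
  })
}

#' Simulate DNase-hypersensitive sites around planted peaks
#'
#' A `dhs_overlap_rate` fraction of peaks (Bernoulli per peak) receive a
#' DHS interval placed within +/-1 kb of the peak; one far DHS per
#' remaining peak is placed uniformly at least 5 kb away from every
#' planted peak (rejection sampling; a warning is emitted and the best
#' effort kept if a chromosome is too crowded).
#'
#' @param genome named character vector of sequences or named lengths.
#' @param true_peaks planted-peak data.frame.
#' @param config a [synth_config()].
#' @return list with `dhs` (chrom, start, end) and `flags` (peak_id,
#'   dhs: logical truth flag).
#' @export
simulate_dhs <- function(genome, true_peaks, config) {
  stopifnot(inherits(config, "synth_config"))
  lens <- chrom_lengths(genome)
  margin <- 1000
  dl <- config$dhs_length
  n <- nrow(true_peaks)
  with_seed_if(derive_seed(config$seed, "dhs"), {
    flagged <- runif(n) < config$dhs_overlap_rate
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ch <- true_peaks$chrom[i]; L <- lens[[ch]]
      if (flagged[i]) {
        lo <- max(0, true_peaks$start[i] - margin)
        hi <- min(L - dl, true_peaks$end[i] + margin - dl)
        s <- floor(runif(1, lo, max(lo + 1, hi)))
      } else {
        pk <- true_peaks[true_peaks$chrom == ch, , drop = FALSE]
        s <- NA
        for (try in seq_len(1000)) {
          cand <- floor(runif(1, 0, L - dl))
          if (all(cand + dl + 5000 <= pk$start | cand >= pk$end + 5000)) {
            s <- cand; break
          }
        }
        if (is.na(s)) {
          warning("no position >= 5 kb from all peaks on ", ch,
                  "; placing a far DHS at best effort")
          s <- floor(runif(1, 0, L - dl))
        }
      }
      rows[[i]] <- data.frame(chrom = ch, start = s, end = s + dl,
                              stringsAsFactors = FALSE)
    }
    dhs <- do.call(rbind, rows)
    dhs <- dhs[order(dhs$chrom, dhs$start), , drop = FALSE]
    rownames(dhs) <- NULL
    list(dhs = dhs,
         flags = data.frame(peak_id = true_peaks$peak_id, dhs = flagged,
                            stringsAsFactors = FALSE))
  })
}
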