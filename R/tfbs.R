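#' Matrix similarity score of a window against a PWM
#'
#' Information-weighted, min-max-normalized similarity in [0, 1]: with
#' per-column information weights I(i) = sum_b f(i,b) ln(4 f(i,b)), the
#' raw score of a window is sum_i I(i) f(i, b_i), rescaled so that the
#' column-wise argmax word scores 1 and the column-wise argmin word
#' scores 0.
#'
#' @param x a [pwm()].
#' @param window sequence of length `x$width` (ACGT only).
#' @return score in [0, 1]; NA for windows containing non-ACGT letters.
#' @export
match_score <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  if (nchar(window) != x$width) stop("window length must equal PWM width")
  e <- encode_dna(window)
  if (any(e < 0)) return(NA_real_)
  V <- match_weights(x)
  cur <- sum(V[cbind(e + 1L, seq_len(x$width))])
  (cur - attr(V, "min")) / (attr(V, "max") - attr(V, "min"))
}

## Additive per-(base, column) weights I(i) * f(i, b) for Match-style
## scoring, with the min/max attainable sums attached. f is the raw
## column frequency; 0 * ln(0) is taken as 0.
match_weights <- function(x) {
  f <- sweep(x$counts, 2, pmax(colSums(x$counts), 1e-12), "/")
  lf <- ifelse(f > 0, log(4 * f), 0)
  I <- colSums(f * lf)
  V <- sweep(f, 2, I, "*")
  lo <- sum(apply(V, 2, min)); hi <- sum(apply(V, 2, max))
  if (hi - lo < 1e-12) {
    stop("uninformative PWM: all words score identically")
  }
  structure(V, min = lo, max = hi)
}

#' Scan a sequence for PWM matches above a similarity threshold
#'
#' All windows with [match_score()] >= `threshold` are reported; with
#' `both_strands`, the reverse strand is scanned as well (hits keep
#' forward-strand offsets). Windows containing non-ACGT letters are
#' ineligible.
#'
#' @param sequence DNA string.
#' @param x a [pwm()].
#' @param threshold similarity threshold in [0, 1].
#' @param both_strands scan the reverse complement too.
#' @return data.frame (offset, strand, score), 0-based offsets.
#' @export
scan_pwm <- function(sequence, x, threshold = 0.85, both_strands = TRUE) {
  stopifnot(inherits(x, "pwm"))
  V <- match_weights(x)
  lo <- attr(V, "min"); hi <- attr(V, "max")
  e <- encode_dna(sequence)
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    W <- if (st == "+") V else V[4:1, ncol(V):1, drop = FALSE]
    sc <- cpp_window_scores(e, W)
    sc <- (sc - lo) / (hi - lo)
    i <- which(!is.na(sc) & sc >= threshold)
    if (length(i)) {
      hits[[st]] <- data.frame(offset = i - 1L, strand = st,
                               score = sc[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(0), strand = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## hit count of one pwm over many sequences (C++ bulk path)
scan_count_many <- function(sequences_enc, x, threshold, both_strands = TRUE) {
  V <- match_weights(x)
  lo <- attr(V, "min"); hi <- attr(V, "max")
  thr_abs <- lo + threshold * (hi - lo) - 1e-12
  Vr <- V[4:1, ncol(V):1, drop = FALSE]
  sum(vapply(sequences_enc, function(e) {
    n <- cpp_scan_stats(e, V, thr_abs)[1]
    if (both_strands) n <- n + cpp_scan_stats(e, Vr, thr_abs)[1]
    n
  }, numeric(1)))
}

#' Sample length- and chromosome-matched control intervals
#'
#' For each peak and each of `n_sets` control sets, one interval of the
#' same length is placed uniformly on the same chromosome, avoiding
#' overlap with any peak by rejection sampling (after `max_tries`
#' failures a warning is emitted and the overlap allowed).
#'
#' @param peaks peak data.frame (chrom, start, end).
#' @param genome named character vector of sequences or named lengths.
#' @param n_sets number of control sets.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per interval.
#' @return list of `n_sets` interval data.frames, rows parallel to
#'   `peaks`.
#' @export
sample_controls <- function(peaks, genome, n_sets = 10, seed = NULL,
                            max_tries = 1000) {
  lens <- chrom_lengths(genome)
  widths <- peaks$end - peaks$start
  if (any(widths > lens[peaks$chrom])) {
    stop("peak longer than its chromosome")
  }
  by_ch <- split(seq_len(nrow(peaks)), peaks$chrom)
  with_seed_if(seed, {
    lapply(seq_len(n_sets), function(b) {
      start <- numeric(nrow(peaks))
      for (ch in names(by_ch)) {
        idx <- by_ch[[ch]]
        pk <- peaks[idx, , drop = FALSE]
        L <- lens[[ch]]
        for (i in idx) {
          w <- peaks$end[i] - peaks$start[i]
          placed <- FALSE
          for (t in seq_len(max_tries)) {
            s <- floor(runif(1, 0, L - w + 1))
            if (all(s + w <= pk$start | s >= pk$end)) {
              placed <- TRUE; break
            }
          }
          if (!placed) {
            warning("control placement retries exhausted on ", ch,
                    "; allowing peak overlap")
          }
          start[i] <- s
        }
      }
      data.frame(chrom = peaks$chrom, start = start,
                 end = start + widths, stringsAsFactors = FALSE)
    })
  })
}

#' Extract interval sequences from a genome
#'
#' @param genome named character vector of sequences.
#' @param intervals data.frame (chrom, start, end), 0-based half-open.
#' @return character vector of sequences, one per interval.
#' @export
extract_sequences <- function(genome, intervals) {
  stopifnot(is.character(genome))
  substr_v <- function(ch, s, e) substring(genome[[ch]], s + 1, e)
  mapply(substr_v, intervals$chrom, intervals$start, intervals$end,
         USE.NAMES = FALSE)
}

#' Chi-square TFBS enrichment against randomized controls
#'
#' Per PWM, the observed frequency O is the total hit count over the
#' peak sequences and the expected frequency E the mean total over the
#' control sets; the discrepancy is evaluated as a one-cell
#' goodness-of-fit chi-square (O - E)^2 / E on 1 degree of freedom
#' (upper tail). E = 0 with O > 0 is flagged and given the smallest
#' representable p. A 2x2 hit/non-hit variant (sequences with >= 1 hit
#' vs without) is available via `statistic = "2x2"`.
#'
#' @param peak_seqs character vector of peak sequences.
#' @param control_sets list of character vectors (one per control set).
#' @param pwms list of [pwm()] objects.
#' @param threshold matrix similarity threshold for [scan_pwm()].
#' @param alpha significance level on the raw p-value.
#' @param cap_per_seq count at most one hit per sequence.
#' @param statistic "goodness" (default) or "2x2".
#' @param bonferroni apply Bonferroni correction across the library.
#' @return data.frame (tf, observed_hits, expected_hits, chi2, p,
#'   significant), sorted by p.
#' @export
chi_square_enrichment <- function(peak_seqs, control_sets, pwms,
                                  threshold = 0.85, alpha = 0.0005,
                                  cap_per_seq = FALSE,
                                  statistic = c("goodness", "2x2"),
                                  bonferroni = FALSE) {
  statistic <- match.arg(statistic)
  if (!length(pwms)) stop("empty PWM library")
  if (!length(control_sets)) stop("need at least 1 control set")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  enc_p <- lapply(peak_seqs, encode_dna)
  enc_c <- lapply(control_sets, function(s) lapply(s, encode_dna))
  count_set <- function(enc, x) {
    if (!cap_per_seq) return(scan_count_many(enc, x, threshold))
    V <- match_weights(x)
    thr_abs <- attr(V, "min") +
      threshold * (attr(V, "max") - attr(V, "min")) - 1e-12
    Vr <- V[4:1, ncol(V):1, drop = FALSE]
    sum(vapply(enc, function(e) {
      (cpp_scan_stats(e, V, thr_abs)[1] +
         cpp_scan_stats(e, Vr, thr_abs)[1]) > 0
    }, logical(1)))
  }
  rows <- lapply(pwms, function(x) {
    O <- count_set(enc_p, x)
    Eb <- vapply(enc_c, count_set, numeric(1), x = x)
    E <- mean(Eb)
    if (statistic == "goodness") {
      if (E == 0 && O == 0) {
        chi2 <- 0; p <- 1; flag <- FALSE
      } else if (E == 0) {
        chi2 <- Inf; p <- .Machine$double.xmin; flag <- TRUE
      } else {
        chi2 <- (O - E)^2 / E
        p <- pchisq(chi2, df = 1, lower.tail = FALSE)
        flag <- FALSE
      }
    } else {
      n1 <- length(enc_p); n0 <- sum(lengths(enc_c))
      h1 <- min(O, n1); h0 <- min(sum(Eb), n0)
      m <- matrix(c(h1, n1 - h1, h0, n0 - h0), 2)
      chi2 <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
      chi2 <- unname(chi2)
      p <- pchisq(chi2, df = 1, lower.tail = FALSE)
      flag <- FALSE
    }
    data.frame(tf = x$id, observed_hits = O, expected_hits = E,
               chi2 = chi2, p = p, zero_expected = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  padj <- if (bonferroni) pmin(out$p * length(pwms), 1) else out$p
  out$significant <- padj < alpha
  out <- out[order(out$p, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a degenerate consensus pattern
#'
#' Bracket expressions such as `AG[GA][GT]GG[CAT][GAT][CG]` expand to a
#' finite word set; the reverse complement can be included when
#' scanning.
#'
#' @param pattern bracket expression over A/C/G/T.
#' @param include_revcomp also match the reverse-complement words.
#' @return an object of class `consensus_pattern` with per-position
#'   base sets, width, and the equivalent IUPAC string.
#' @export
consensus_pattern <- function(pattern, include_revcomp = TRUE) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list(); i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      grp <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        grp <- c(grp, chars[j]); j <- j + 1
      }
      if (j > length(chars)) stop("unclosed '[' at position ", i)
      if (!length(grp)) stop("empty bracket at position ", i)
      sets[[length(sets) + 1L]] <- grp
      i <- j + 1
    } else if (ch == "]") {
      stop("unmatched ']' at position ", i)
    } else {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1
    }
  }
  for (k in seq_along(sets)) {
    bad <- setdiff(sets[[k]], BASES)
    if (length(bad)) {
      stop("invalid base '", bad[1], "' in pattern position ", k)
    }
    if (anyDuplicated(sets[[k]])) sets[[k]] <- unique(sets[[k]])
  }
  structure(list(pattern = pattern, sets = sets, width = length(sets),
                 include_revcomp = include_revcomp,
                 iupac = sets_to_iupac(sets)),
            class = "consensus_pattern")
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", AC = "M", AG = "R",
               AT = "W", CG = "S", CT = "Y", GT = "K", ACG = "V",
               ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

sets_to_iupac <- function(sets) {
  paste(vapply(sets, function(s) {
    key <- paste(sort(s), collapse = "")
    unname(IUPAC_MAP[key])
  }, character(1)), collapse = "")
}

#' Enumerate all words of a consensus pattern
#'
#' @param pattern a [consensus_pattern()] or bracket-expression string.
#' @param with_revcomp include the reverse-complement words.
#' @return character vector of distinct words.
#' @export
expand_consensus <- function(pattern, with_revcomp = FALSE) {
  if (is.character(pattern)) pattern <- consensus_pattern(pattern)
  grid <- do.call(expand.grid,
                  c(rev(pattern$sets), stringsAsFactors = FALSE))
  words <- do.call(paste0, rev(grid))
  if (with_revcomp) words <- unique(c(words, revcomp(words)))
  words
}

#' Scan sequences for a degenerate consensus pattern
#'
#' Exact degenerate-word matching at every offset (overlapping matches
#' counted) of the pattern and, when flagged, its reverse complement.
#' Non-ACGT letters in the subject never match.
#'
#' @param sequences character vector of sequences.
#' @param pattern a [consensus_pattern()] or bracket-expression string.
#' @return list with `counts` (per-sequence match counts), `fraction`
#'   (sequences with >= 1 match) and `flags`.
#' @export
scan_consensus <- function(sequences, pattern) {
  if (is.character(pattern)) pattern <- consensus_pattern(pattern)
  subj <- Biostrings::DNAStringSet(toupper(sequences))
  cnt <- Biostrings::vcountPattern(pattern$iupac, subj,
                                   fixed = c(pattern = FALSE,
                                             subject = TRUE))
  if (pattern$include_revcomp) {
    rc <- revcomp(pattern$iupac)
    cnt <- cnt + Biostrings::vcountPattern(rc, subj,
                                           fixed = c(pattern = FALSE,
                                                     subject = TRUE))
  }
  list(counts = cnt, fraction = mean(cnt > 0), flags = cnt > 0)
}

#' Generate a synthetic PWM library
#'
#' Random count matrices emulating a transcription-factor matrix
#' collection: each column concentrates on a random base at a random
#' identity level. Purely synthetic; stands in for licensed matrix
#' libraries in examples and benchmarks.
#'
#' @param n number of matrices.
#' @param width motif width (recycled; may be a range sampled per
#'   matrix).
#' @param n_sites nominal site count per matrix.
#' @param identity dominant-base fraction range.
#' @param seed RNG seed.
#' @return list of [pwm()] objects with ids TF001, TF002, ...
#' @export
random_pwm_library <- function(n, width = 10, n_sites = 20,
                               identity = c(0.7, 0.95), seed = NULL) {
  with_seed_if(seed, {
    lapply(seq_len(n), function(i) {
      w <- if (length(width) > 1) sample(width, 1) else width
      counts <- vapply(seq_len(w), function(j) {
        p <- rep((1 - runif(1, identity[1], identity[2])) / 3, 4)
        p[sample.int(4, 1)] <- runif(1, identity[1], identity[2])
        as.numeric(stats::rmultinom(1, n_sites, p))
      }, numeric(4))
      pwm(counts, id = sprintf("TF%03d", i))
    })
  })
}

#' PWM concentrated on a consensus word
#'
#' @param word consensus string (ACGT).
#' @param identity per-column weight of the consensus base.
#' @param n_sites nominal site count.
#' @param id matrix identifier.
#' @return a [pwm()].
#' @export
pwm_from_consensus <- function(word, identity = 0.9, n_sites = 100,
                               id = word) {
  e <- encode_dna(word)
  stopifnot(all(e >= 0))
  counts <- vapply(e, function(b) {
    p <- rep((1 - identity) / 3 * n_sites, 4)
    p[b + 1] <- identity * n_sites
    p
  }, numeric(4))
  pwm(counts, id = id)
}
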