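#' Fixed-width Gibbs-sampling motif discovery
#'
#' One-occurrence-per-sequence site sampler: each sequence carries one
#' candidate site (offset + strand); per iteration each sequence's site
#' is resampled from the likelihood ratio of the motif model built from
#' all other sequences' sites (Dirichlet pseudocounts proportional to
#' the background), on both strands. The best-scoring state across all
#' iterations is returned; every 100 iterations a phase-shift move
#' slides all sites by up to 3 bp if that improves the score. The motif
#' score is F = sum over columns and bases of c * log(q / p) with c the
#' site counts, q the pseudocounted frequencies and p the background.
#'
#' @param sequences character vector of DNA sequences (>= 2 usable).
#' @param width motif width in bp.
#' @param iterations number of sampler sweeps.
#' @param seed RNG seed (NULL: use the current RNG stream).
#' @param background length-4 base frequencies; default is the 0-order
#'   composition of the input sequences.
#' @param pseudocount total Dirichlet pseudocount per column, spread as
#'   `pseudocount * background`.
#' @param phase_every iterations between phase-shift moves (0 disables).
#' @return an object of class `motif_model`: list with `pwm` (site-count
#'   [pwm()]), `sites` (data.frame seq, offset, strand), `score`,
#'   `initial_score` and `background`.
#' @export
gibbs_sample <- function(sequences, width = 12, iterations = 5000,
                         seed = NULL, background = NULL, pseudocount = 1,
                         phase_every = 100) {
  stopifnot(width >= 2)
  usable <- nchar(sequences) >= width
  if (any(!usable)) {
    warning(sum(!usable), " sequence(s) shorter than the motif width; excluded")
  }
  seqs <- sequences[usable]
  if (length(seqs) < 2) stop("need at least 2 sequences of length >= width")
  enc <- lapply(seqs, encode_dna)
  if (is.null(background)) {
    tab <- tabulate(unlist(enc) + 1L, nbins = 4)
    background <- (tab + 1) / (sum(tab) + 4)
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6)
  fit <- with_seed_if(seed, {
    cpp_gibbs(enc, as.integer(width), as.integer(iterations),
              as.numeric(background), pseudocount,
              as.integer(phase_every))
  })
  sites <- data.frame(seq = which(usable), offset = fit$offsets,
                      strand = c("+", "-")[fit$strands + 1L],
                      stringsAsFactors = FALSE)
  structure(list(pwm = pwm(fit$counts, id = "gibbs_motif",
                           pseudocount = pseudocount),
                 sites = sites, score = fit$score,
                 initial_score = fit$initial_score,
                 background = background),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> width", x$pwm$width, " consensus",
      pwm_consensus(x$pwm), " score", format(x$score, digits = 5), "\n")
  invisible(x)
}

#' Information content of a PWM in bits
#'
#' Total (and optionally per-column) relative entropy of the
#' pseudocounted column frequencies against the background:
#' sum over columns and bases of q * log2(q / p).
#'
#' @param x a [pwm()].
#' @param background length-4 background frequencies.
#' @param per_column return the per-column vector instead of the total.
#' @return bits (scalar, or per-column numeric vector).
#' @export
information_content <- function(x, background = rep(0.25, 4),
                                per_column = FALSE) {
  stopifnot(inherits(x, "pwm"))
  q <- pwm_freq(x, background)
  if (any(background == 0 & rowSums(q) > 0)) {
    stop("zero background frequency with non-zero PWM frequency")
  }
  ic <- colSums(q * log2(q / background))
  if (per_column) ic else sum(ic)
}

## additive log2-odds weight matrix of a pwm against a background
log_odds_matrix <- function(x, background = rep(0.25, 4)) {
  q <- pwm_freq(x, background)
  log2(q / background)
}

#' Fraction of sequences containing a motif
#'
#' A sequence is flagged when its best log-odds window score (either
#' strand) reaches `threshold_fraction` of the maximal achievable
#' log-odds; values above 1 are clamped to 1, at which only exact
#' consensus matches count.
#'
#' @param x a [pwm()].
#' @param sequences character vector of sequences.
#' @param threshold_fraction fraction of the maximal log-odds score.
#' @param background length-4 background frequencies.
#' @return list with `fraction` and per-sequence logical `flags`.
#' @export
fraction_with_motif <- function(x, sequences, threshold_fraction = 0.8,
                                background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pwm"), length(sequences) > 0)
  W <- log_odds_matrix(x, background)
  Wrc <- W[4:1, ncol(W):1]  # minus strand: complement rows, reverse columns
  maxach <- sum(apply(W, 2, max))
  thr <- min(threshold_fraction, 1) * maxach - 1e-9
  flags <- vapply(sequences, function(s) {
    e <- encode_dna(s)
    if (length(e) < ncol(W)) return(FALSE)
    best <- max(cpp_scan_stats(e, W, thr)[2], cpp_scan_stats(e, Wrc, thr)[2])
    is.finite(best) && best >= thr
  }, logical(1), USE.NAMES = FALSE)
  list(fraction = mean(flags), flags = flags)
}

#' Per-column logo matrix (bits) of a motif model
#'
#' Row j of the result scales column j's base frequencies by that
#' column's information content, so stacking the four values reproduces
#' the column height of a sequence logo.
#'
#' @param model a `motif_model` (or a bare [pwm()]).
#' @param background length-4 background frequencies.
#' @return data.frame (position, A, C, G, T, bits).
#' @export
motif_logo_matrix <- function(model, background = NULL) {
  p <- if (inherits(model, "motif_model")) model$pwm else model
  if (is.null(background)) {
    background <- if (inherits(model, "motif_model")) model$background
    else rep(0.25, 4)
  }
  q <- pwm_freq(p, background)
  ic <- information_content(p, background, per_column = TRUE)
  out <- data.frame(position = seq_len(p$width), t(q * rep(ic, each = 4)))
  names(out) <- c("position", BASES)
  out$bits <- ic
  out
}

#' Write a motif model: TRANSFAC matrix plus a logo bits table
#'
#' @param model a `motif_model`.
#' @param path output path for the TRANSFAC matrix; the bits table goes
#'   to `paste0(path, ".bits.tsv")` unless `bits_path` is given.
#' @param bits_path optional path for the per-column bits table.
#' @return invisibly, the matrix path.
#' @export
write_motif <- function(model, path, bits_path = NULL) {
  stopifnot(inherits(model, "motif_model"))
  write_transfac_matrices(model$pwm, path)
  if (is.null(bits_path)) bits_path <- paste0(path, ".bits.tsv")
  write.table(motif_logo_matrix(model), bits_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
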