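BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' IUPAC ambiguity codes are complemented; any other letter is left
#' unchanged.
#'
#' @param x character vector of sequences (A/C/G/T plus IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  from <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
  to   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"
  vapply(x, function(s) {
    paste(rev(strsplit(chartr(from, to, s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Encode a sequence as 0:3 (A,C,G,T); anything else becomes -1L.
encode_dna <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
  m[is.na(m)] <- 0L
  as.integer(m - 1L)
}

## Run expr under a fixed seed without disturbing the caller's RNG.
## seed = NULL leaves the RNG stream alone.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## Derive a reproducible per-stage seed from a master seed, kept < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

## Largest-remainder apportionment of n among proportions p (sums to 1).
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  k <- floor(raw)
  short <- n - sum(k)
  if (short > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(short)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}

## Named chromosome lengths from a genome that is either a named
## character vector of sequences or already a named numeric of lengths.
chrom_lengths <- function(genome) {
  if (is.character(genome)) {
    setNames(nchar(genome), names(genome))
  } else if (is.numeric(genome)) {
    stopifnot(!is.null(names(genome)))
    genome
  } else {
    stop("genome must be a named character vector of sequences ",
         "or a named numeric vector of chromosome lengths")
  }
}

stop_if_not_df <- function(x, cols, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    stop(what, " must be a data.frame with columns: ",
         paste(cols, collapse = ", "))
  }
}

## Internal 0-based half-open intervals -> IRanges (1-based inclusive).
to_iranges <- function(start, end) IRanges::IRanges(start + 1L, end)

## Population standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
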