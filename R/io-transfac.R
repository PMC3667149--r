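#' Construct a position weight matrix
#'
#' @param counts 4 x width non-negative matrix with rows A, C, G, T.
#' @param id matrix identifier.
#' @param pseudocount positive scalar added (scaled by background) when
#'   converting counts to frequencies.
#' @return an object of class `pwm`.
#' @export
pwm <- function(counts, id = "PWM", pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4) stop("PWM width must be >= 4")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(colSums(counts) + pseudocount <= 0)) stop("empty PWM column")
  rownames(counts) <- BASES
  structure(list(id = id, counts = counts, width = ncol(counts),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$id, " width", x$width, " consensus",
      pwm_consensus(x), "\n")
  invisible(x)
}

#' Column frequencies of a PWM
#'
#' @param x a `pwm`.
#' @param background length-4 background distribution used to spread the
#'   pseudocount across bases; defaults to uniform.
#' @return 4 x width matrix of column frequencies (columns sum to 1).
#' @export
pwm_freq <- function(x, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pwm"), length(background) == 4)
  f <- x$counts + x$pseudocount * background
  sweep(f, 2, colSums(f), "/")
}

#' Column-wise argmax consensus of a PWM
#'
#' @param x a `pwm`.
#' @return consensus string (ties broken by A<C<G<T order).
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read PWMs from a TRANSFAC-style matrix flat file
#'
#' Parses `ID`-headed blocks whose numbered rows (after a `P0` header
#' line) carry one count per base in A, C, G, T order; integer or real
#' counts are accepted. Ragged rows are reported with line numbers.
#'
#' @param path path to the matrix file.
#' @param pseudocount pseudocount attached to every matrix.
#' @return list of `pwm` objects.
#' @export
read_transfac_matrices <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  mats <- list()
  id <- NULL; rows <- NULL; in_matrix <- FALSE
  flush <- function() {
    if (is.null(id)) return()
    if (is.null(rows) || nrow(rows) < 4) {
      stop("TRANSFAC matrix ", id, ": fewer than 4 positions")
    }
    mats[[length(mats) + 1L]] <<- pwm(t(rows), id = id,
                                      pseudocount = pseudocount)
    id <<- NULL; rows <<- NULL; in_matrix <<- FALSE
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^ID\\b", ln)) {
      flush()
      id <- sub("^ID\\s+", "", ln)
      next
    }
    if (grepl("^P0\\b", ln) || grepl("^PO\\b", ln)) { in_matrix <- TRUE; next }
    if (!is.null(id) && grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (length(f) < 5 || anyNA(vals)) {
        stop("TRANSFAC line ", i, ": expected 4 numeric counts, got '",
             ln, "'")
      }
      rows <- rbind(rows, vals)
    }
  }
  flush()
  if (!length(mats)) stop("no matrices found in ", path)
  mats
}

#' Write PWMs in TRANSFAC matrix flat-file format
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_transfac_matrices <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms) {
    stopifnot(inherits(m, "pwm"))
    writeLines(c(paste("ID", m$id), "P0      A      C      G      T"), con)
    cons <- strsplit(pwm_consensus(m), "")[[1]]
    for (j in seq_len(m$width)) {
      writeLines(sprintf("%02d %.12g %.12g %.12g %.12g %s", j,
                         m$counts[1, j], m$counts[2, j], m$counts[3, j],
                         m$counts[4, j], cons[j]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
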