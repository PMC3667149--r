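#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; non-ACGT letters are preserved (they
#' are simply never eligible for motif matching downstream). Duplicate
#' record ids and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record, in file order.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(toupper(as.character(seqs)), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' Sequences are uppercased; record order is preserved.
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  x <- Biostrings::BStringSet(toupper(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
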