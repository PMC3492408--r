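#' Read protein sequences from FASTA
#'
#' Reads a (multi-record) FASTA file into a tidy sequence table. Records are
#' upper-cased, a single terminal stop ('*') is stripped, and the alphabet
#' is validated: the 20 standard one-letter codes plus 'X' for an unknown
#' residue are accepted; anything else is a format error naming the
#' offending record and position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record, in file order: \code{id}
#'   (first word of the header), \code{residues}, \code{length}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p", "GSG"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta(): no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("read_fasta(): empty FASTA: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  res <- unname(toupper(as.character(set)))
  res <- sub("\\*$", "", res)
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX]*$"
  for (i in seq_along(res)) {
    if (!grepl(ok, res[i])) {
      chars <- strsplit(res[i], "", fixed = TRUE)[[1]]
      bad <- which(!chars %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))[1]
      stop("read_fasta(): record '", ids[i], "' has non-amino-acid character '",
           chars[bad], "' at position ", bad, call. = FALSE)
    }
  }
  tibble::tibble(id = ids, residues = res, length = nchar(res))
}

#' Write a sequence table to FASTA
#'
#' @param sequences Tibble with \code{id} and \code{residues} columns
#'   (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  set <- Biostrings::BStringSet(sequences$residues)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
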