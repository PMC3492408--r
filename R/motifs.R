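#' Compile a PROSITE-style fixed-length consensus pattern
#'
#' Supported dialect: upper-case single residues, \code{X} as the
#' any-residue wildcard, and bracketed residue classes written either
#' \code{[RK]} or \code{[R/K]}. Only fixed-length patterns are supported
#' (no \code{x(2,4)} repeats): the nucleotide-binding consensus motifs this
#' package targets -- Walker-A \code{GXGXXG}, the partial Walker-B
#' \code{[R/K]XXXGXXXL} and the GroES-type \code{Y[G/A/S/T][V/G][K/T/Q/S/N]}
#' -- are all fixed-length.
#'
#' @param text Pattern string in the dialect above.
#' @param id Pattern identifier; defaults to the canonical rendering.
#' @return An object of class \code{motif_pattern}: a list with \code{id},
#'   \code{elements} (one character vector of allowed residues per position;
#'   \code{NA} marks the wildcard), \code{length} and \code{text} (canonical
#'   rendering; compiling it reproduces the pattern).
#' @export
#' @examples
#' compile_pattern("GXGXXG")
#' compile_pattern("[R/K]XXXGXXXL")
compile_pattern <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= length(chars)) {
        if (chars[j] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close)) {
        stop("compile_pattern(): unclosed '[' at position ", i, " in '",
             text, "'", call. = FALSE)
      }
      members <- setdiff(chars[(i + 1L):(close - 1L)], "/")
      if (close == i + 1L || length(members) == 0L) {
        stop("compile_pattern(): empty class at position ", i, " in '",
             text, "'", call. = FALSE)
      }
      bad <- setdiff(members, standard)
      if (length(bad)) {
        stop("compile_pattern(): illegal residue '", bad[1],
             "' in class at position ", i, call. = FALSE)
      }
      elements[[length(elements) + 1L]] <- sort(unique(members))
      i <- close + 1L
    } else if (ch == "X") {
      elements[[length(elements) + 1L]] <- NA_character_
      i <- i + 1L
    } else if (ch %in% standard) {
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("compile_pattern(): illegal character '", ch, "' at position ", i,
           " in '", text, "'", call. = FALSE)
    }
  }
  if (length(elements) == 0L) {
    stop("compile_pattern(): empty pattern", call. = FALSE)
  }
  canon <- vapply(elements, function(e) {
    if (length(e) == 1L && is.na(e)) "X"
    else if (length(e) == 1L) e
    else paste0("[", paste(e, collapse = "/"), "]")
  }, character(1))
  structure(
    list(id = if (is.null(id)) paste(canon, collapse = "") else id,
         elements = elements,
         length = length(elements),
         text = paste(canon, collapse = "")),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$id, ": ", x$text,
      " (", x$length, " positions)\n", sep = "")
  invisible(x)
}

#' Built-in nucleotide-binding consensus patterns
#'
#' The three consensus motifs used to flag candidate ATP-binding sites:
#' the Walker-A glycine-rich loop \code{GXGXXG}, a partial Walker-B
#' \code{[R/K]XXXGXXXL}, and the 4-residue GroES-type motif
#' \code{Y[G/A/S/T][V/G][K/T/Q/S/N]} from the chaperonin that binds but
#' does not hydrolyse ATP.
#'
#' @return Named list of \code{motif_pattern} objects keyed
#'   \code{WALKER_A}, \code{WALKER_B_PARTIAL}, \code{GROES}.
#' @export
builtin_patterns <- function() {
  list(
    WALKER_A         = compile_pattern("GXGXXG", id = "WALKER_A"),
    WALKER_B_PARTIAL = compile_pattern("[R/K]XXXGXXXL", id = "WALKER_B_PARTIAL"),
    GROES            = compile_pattern("Y[G/A/S/T][V/G][K/T/Q/S/N]", id = "GROES")
  )
}

# internal: regex character class for one pattern element
element_regex <- function(e, permissive_x) {
  standard <- "ACDEFGHIKLMNPQRSTVWY"
  if (length(e) == 1L && is.na(e)) {
    if (permissive_x) paste0("[", standard, "X]") else paste0("[", standard, "]")
  } else {
    paste0("[", paste(e, collapse = ""), if (permissive_x) "X", "]")
  }
}

#' Scan sequences for consensus-motif hits
#'
#' Tests every window of each pattern's length and reports all hits,
#' including mutually overlapping ones (a scanner that advances past a
#' match would miss overlapping pairs such as two Walker-A motifs two
#' residues apart). Hits are neither merged nor deduplicated across
#' patterns; downstream inference decides containment.
#'
#' An 'X' in the sequence matches nothing by default -- neither the
#' wildcard nor a class -- so ambiguous Edman reads cannot generate
#' spurious hits; set \code{permissive_x = TRUE} to let sequence 'X' match
#' any pattern position.
#'
#' @param sequences Sequence tibble from [read_fasta()] (or a single
#'   residue string).
#' @param patterns A \code{motif_pattern}, a list of them, or pattern
#'   strings to compile.
#' @param permissive_x Should an 'X' residue in the sequence match pattern
#'   positions? Default \code{FALSE}.
#' @return Tibble of hits sorted by (seq_id, start, pattern_id):
#'   \code{seq_id}, \code{pattern_id}, \code{start}, \code{end} (1-based
#'   inclusive), \code{matched} (the residue substring).
#' @export
#' @examples
#' scan_motifs("GAGAAGAG", "GXGXXG")
scan_motifs <- function(sequences, patterns = builtin_patterns(),
                        permissive_x = FALSE) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(id = "seq", residues = toupper(sequences),
                                length = nchar(sequences))
  }
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  patterns <- lapply(patterns, function(p) {
    if (inherits(p, "motif_pattern")) p else compile_pattern(p)
  })
  rows <- purrr::map_dfr(seq_len(nrow(sequences)), function(si) {
    res <- sequences$residues[si]
    purrr::map_dfr(patterns, function(p) {
      rx <- paste0("(?=(", paste(
        vapply(p$elements, element_regex, character(1),
               permissive_x = permissive_x), collapse = ""), "))")
      m <- gregexpr(rx, res, perl = TRUE)[[1]]
      if (m[1] == -1L) return(tibble::tibble())
      starts <- as.integer(m)
      tibble::tibble(
        seq_id = sequences$id[si],
        pattern_id = p$id,
        start = starts,
        end = starts + p$length - 1L,
        matched = substring(res, starts, starts + p$length - 1L)
      )
    })
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(seq_id = character(), pattern_id = character(),
                          start = integer(), end = integer(),
                          matched = character()))
  }
  dplyr::arrange(rows, .data$seq_id, .data$start, .data$pattern_id)
}
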