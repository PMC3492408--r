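#' Decode an Edman N-terminal read
#'
#' Edman degradation reads use 'X' for an unidentified cycle, a
#' parenthesised residue like \code{(A)} for a low-confidence call, and
#' \code{-} for a skipped cycle. Low-confidence calls, 'X' and '-' are all
#' treated as wildcards when anchoring the read on the protein: a
#' parenthesised call may simply be wrong, so it must not veto a position.
#'
#' @param read Read string, e.g. \code{"(E)GLDFPEYD(G)"}.
#' @return Character vector, one element per sequencing cycle; \code{NA}
#'   marks a wildcard position.
#' @export
#' @examples
#' decode_read("AVVAXFRMTP")
#' decode_read("(E)GLDFPEYD(G)")
decode_read <- function(read) {
  stopifnot(is.character(read), length(read) == 1L)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(close)) stop("decode_read(): unclosed '(' in '", read, "'",
                             call. = FALSE)
      out <- c(out, NA_character_)  # low-confidence call -> wildcard
      i <- close + 1L
    } else if (ch %in% c("X", "-")) {
      out <- c(out, NA_character_)
      i <- i + 1L
    } else if (toupper(ch) %in% standard) {
      out <- c(out, toupper(ch))
      i <- i + 1L
    } else {
      stop("decode_read(): illegal character '", ch, "' in '", read, "'",
           call. = FALSE)
    }
  }
  if (length(out) == 0L) stop("decode_read(): empty read", call. = FALSE)
  out
}

#' Locate an N-terminal read on a protein sequence
#'
#' Finds all positions where the decoded read matches: confident calls
#' exactly, wildcard cycles (low-confidence calls, 'X', skipped cycles)
#' match any residue. In strict mode (default) a candidate must sit at a
#' cleavage junction -- position 1 or preceded by an unblocked K/R -- since
#' a tryptic fragment's N-terminus can only arise at a cut.
#'
#' Zero candidates means the read could not be located; more than one is
#' reported as-is, never silently resolved.
#'
#' @param sequence Sequence tibble row or residue string.
#' @param read Edman read string (see [decode_read()]).
#' @param min_length Minimum decoded read length for anchoring (default 5;
#'   shorter reads cannot anchor uniquely in a large protein).
#' @param strict Require candidates to sit at cleavage junctions.
#' @param rule Protease rule for junction checking.
#' @return Integer vector of candidate 1-based start positions.
#' @export
locate_n_terminus <- function(sequence, read, min_length = 5L,
                              strict = TRUE, rule = "trypsin") {
  residues <- as_residue_string(sequence)
  decoded <- decode_read(read)
  if (length(decoded) < min_length) {
    stop("locate_n_terminus(): decoded read has ", length(decoded),
         " positions; at least ", min_length, " required for anchoring",
         call. = FALSE)
  }
  rx <- paste0("(?=(", paste(
    ifelse(is.na(decoded), "[ACDEFGHIKLMNPQRSTVWY]", decoded),
    collapse = ""), "))")
  m <- gregexpr(rx, residues, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m)
  if (strict) {
    sites <- cleavage_sites(residues, rule)
    starts <- starts[starts == 1L | (starts - 1L) %in% sites]
  }
  starts
}

#' Rank candidate C-termini for an observed fragment
#'
#' Given a located N-terminus and the apparent gel mass, enumerates every
#' admissible C-terminus -- each predicted cleavage site at or beyond the
#' start, plus the protein terminus (limited proteolysis makes any such
#' span observable) -- keeps those whose calculated mass is within a
#' relative tolerance of the apparent mass, and ranks them by mass error,
#' ties broken toward the larger fragment.
#'
#' The default tolerance of 0.15 reflects how noisy SDS-PAGE apparent
#' masses are relative to sequence-calculated masses: discrepancies of
#' ~9\% occur in practice, so a 10\% tolerance would be too tight.
#'
#' @param sequence Sequence tibble row or residue string.
#' @param start Located 1-based N-terminal position.
#' @param apparent_kda Apparent gel mass, kDa.
#' @param sites Cleavage sites; computed with \code{rule} when omitted.
#' @param tolerance Maximum relative mass error, in (0, 0.5).
#' @param rule Protease rule.
#' @param table Mass table.
#' @return Tibble of candidates ranked by \code{candidate_rank}:
#'   \code{start}, \code{end}, \code{calc_mass_da}, \code{calc_kda},
#'   \code{mass_error_fraction}. Zero rows (with a warning reporting the
#'   nearest miss) when nothing falls within tolerance.
#' @export
assign_c_terminus <- function(sequence, start, apparent_kda, sites = NULL,
                              tolerance = 0.15, rule = "trypsin",
                              table = aa_mass_table()) {
  residues <- as_residue_string(sequence)
  stopifnot(tolerance > 0, tolerance < 0.5, apparent_kda > 0)
  n <- nchar(residues)
  if (start < 1L || start > n) stop("assign_c_terminus(): start out of range",
                                    call. = FALSE)
  if (is.null(sites)) sites <- cleavage_sites(residues, rule)
  ends <- sort(unique(c(sites[sites >= start], n)))
  mass <- vapply(ends, function(e) segment_mass(residues, start, e, table = table),
                 numeric(1))
  cand <- tibble::tibble(
    start = as.integer(start),
    end = as.integer(ends),
    calc_mass_da = mass,
    calc_kda = round_kda(mass),
    mass_error_fraction = abs(mass / 1000 - apparent_kda) / apparent_kda
  )
  keep <- dplyr::filter(cand, .data$mass_error_fraction <= tolerance)
  if (nrow(keep) == 0L) {
    nearest <- cand[which.min(cand$mass_error_fraction), ]
    warning("assign_c_terminus(): unassignable at tolerance ", tolerance,
            "; nearest miss end=", nearest$end, " (calc ", nearest$calc_kda,
            " kDa, error ", signif(nearest$mass_error_fraction, 3), ")",
            call. = FALSE)
    return(dplyr::mutate(keep[0, ], candidate_rank = integer()))
  }
  keep <- dplyr::arrange(keep, .data$mass_error_fraction, dplyr::desc(.data$end))
  dplyr::mutate(keep, candidate_rank = dplyr::row_number())
}

#' Assign a table of observed fragments to protein coordinates
#'
#' Tabular front end over [locate_n_terminus()] and [assign_c_terminus()].
#' Each observed fragment carries an Edman N-terminal read and an apparent
#' gel mass; the assigner anchors the read, ranks candidate C-termini by
#' mass agreement, and reports the chosen span with its mass error and
#' rank.
#'
#' Prior knowledge can pin assignments: a non-\code{NA} \code{known_start}
#' skips read anchoring (required for N-terminally blocked fragments with
#' no read), and a \code{known_end} selects that end from the candidate
#' list (recording the rank it would have had) rather than taking rank 1 --
#' this mirrors how gel fragments are disambiguated against previously
#' characterised digests. Fragments with neither a read nor a known span
#' pass through unassigned (status \code{"no_span"}); they can still
#' participate in parentage-based inference.
#'
#' @param sequence Sequence tibble row or residue string.
#' @param observed Tibble with columns \code{fragment_id},
#'   \code{apparent_kda}, \code{nterm_read}, \code{labeled}, and optionally
#'   \code{parent_id}, \code{known_start}, \code{known_end}.
#' @param tolerance Relative mass tolerance (see [assign_c_terminus()]).
#' @param strict Strict junction anchoring for [locate_n_terminus()].
#' @param rule Protease rule.
#' @param table Mass table.
#' @return Tibble: \code{fragment_id}, \code{apparent_kda}, \code{start},
#'   \code{end}, \code{calc_kda}, \code{mass_error_fraction},
#'   \code{candidate_rank}, \code{n_start_candidates}, \code{labeled},
#'   \code{parent_id}, \code{status} (\code{"assigned"},
#'   \code{"pinned"}, \code{"ambiguous_start"}, \code{"not_located"},
#'   \code{"unassignable"} or \code{"no_span"}).
#' @export
assign_fragments <- function(sequence, observed, tolerance = 0.15,
                             strict = TRUE, rule = "trypsin",
                             table = aa_mass_table()) {
  residues <- as_residue_string(sequence)
  stopifnot(all(c("fragment_id", "apparent_kda", "nterm_read", "labeled")
                %in% names(observed)))
  observed$fragment_id <- as.character(observed$fragment_id)
  if (!"parent_id" %in% names(observed)) observed$parent_id <- NA_character_
  observed$parent_id <- as.character(observed$parent_id)
  if (!"known_start" %in% names(observed)) observed$known_start <- NA_integer_
  if (!"known_end" %in% names(observed)) observed$known_end <- NA_integer_
  sites <- cleavage_sites(residues, rule)

  purrr::map_dfr(seq_len(nrow(observed)), function(i) {
    row <- observed[i, ]
    out <- tibble::tibble(
      fragment_id = row$fragment_id, apparent_kda = row$apparent_kda,
      start = NA_integer_, end = NA_integer_, calc_kda = NA_integer_,
      mass_error_fraction = NA_real_, candidate_rank = NA_integer_,
      n_start_candidates = NA_integer_,
      labeled = row$labeled, parent_id = row$parent_id, status = "no_span"
    )
    has_read <- !is.na(row$nterm_read) && nzchar(row$nterm_read) &&
      toupper(row$nterm_read) != "ND"
    if (has_read && length(decode_read(row$nterm_read)) < 5L) {
      out$status <- "read_too_short"
      return(out)
    }

    if (!is.na(row$known_start)) {
      start <- as.integer(row$known_start)
      out$n_start_candidates <- 1L
      if (has_read) {  # read, if present, must agree with the pinned start
        hits <- locate_n_terminus(residues, row$nterm_read,
                                  strict = strict, rule = rule)
        out$n_start_candidates <- length(hits)
        if (!start %in% hits) {
          out$status <- "not_located"
          return(out)
        }
      }
    } else if (has_read) {
      hits <- locate_n_terminus(residues, row$nterm_read,
                                strict = strict, rule = rule)
      out$n_start_candidates <- length(hits)
      if (length(hits) == 0L) { out$status <- "not_located"; return(out) }
      if (length(hits) > 1L) { out$status <- "ambiguous_start"; return(out) }
      start <- hits[1]
    } else {
      return(out)  # no read, no pinned span
    }

    out$start <- start
    if (!is.na(row$known_end) && is.na(row$apparent_kda)) {
      # fully pinned span, no gel mass to check against
      m <- segment_mass(residues, start, as.integer(row$known_end), table = table)
      out$end <- as.integer(row$known_end)
      out$calc_kda <- round_kda(m)
      out$status <- "pinned"
      return(out)
    }
    cand <- withCallingHandlers(
      assign_c_terminus(residues, start, row$apparent_kda, sites = sites,
                        tolerance = tolerance, table = table),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (nrow(cand) == 0L) { out$status <- "unassignable"; return(out) }
    if (!is.na(row$known_end)) {
      pick <- cand[cand$end == row$known_end, ]
      if (nrow(pick) == 0L) { out$status <- "unassignable"; return(out) }
      out$status <- "pinned"
    } else {
      pick <- cand[1, ]
      out$status <- "assigned"
    }
    out$end <- pick$end
    out$calc_kda <- pick$calc_kda
    out$mass_error_fraction <- pick$mass_error_fraction
    out$candidate_rank <- pick$candidate_rank
    out
  })
}
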