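#' End-to-end binding-region inference
#'
#' Chains the full pipeline: assign observed fragments onto the sequence
#' ([assign_fragments()]), refine labeled spans into candidate regions
#' ([refine_regions()]), scan the sequence for consensus motifs
#' ([scan_motifs()]), and filter hits through regions, topology and
#' exclusions ([filter_motifs()]).
#'
#' @param sequence Sequence tibble row (from [read_fasta()] or
#'   [ryr1_standin()]) or residue string.
#' @param observed Observed-fragment tibble (see [assign_fragments()];
#'   e.g. [ryr1_fragments()]).
#' @param topology Optional topology tibble (e.g. [ryr1_topology()]).
#' @param exclusions Optional exclusion tibble (e.g. [ryr1_exclusions()]).
#' @param patterns Motif patterns to scan (default [builtin_patterns()]).
#' @param tolerance Mass tolerance for C-terminal assignment.
#' @param w C-terminal ambiguity window for subtracted unlabeled spans.
#' @param demote_on_unlabeled_products Apply demotion rule R3.
#' @param strict Strict junction anchoring of N-terminal reads.
#' @return A \code{binding_calls} object (see [filter_motifs()]) with the
#'   fragment assignment tibble attached as \code{$assignments}.
#' @export
#' @examples
#' calls <- call_binding_regions(ryr1_standin(), ryr1_fragments(),
#'                               topology = ryr1_topology(),
#'                               exclusions = ryr1_exclusions())
#' calls
call_binding_regions <- function(sequence, observed,
                                 topology = NULL, exclusions = NULL,
                                 patterns = builtin_patterns(),
                                 tolerance = 0.15, w = 0L,
                                 demote_on_unlabeled_products = TRUE,
                                 strict = TRUE) {
  assignments <- assign_fragments(sequence, observed, tolerance = tolerance,
                                  strict = strict)
  regions <- refine_regions(
    assignments, w = w,
    demote_on_unlabeled_products = demote_on_unlabeled_products)
  hits <- scan_motifs(sequence, patterns)
  calls <- filter_motifs(hits, regions, topology = topology,
                         exclusions = exclusions)
  calls$assignments <- assignments
  calls
}

#' Plot candidate regions and motifs along the sequence
#'
#' Linear map of the protein: candidate regions as filled bars, surviving
#' motifs as upward ticks, excluded motif hits (from the audit) are not
#' drawn -- the plot shows the final call set.
#'
#' @param object A \code{binding_calls} object.
#' @param sequence_length Optional protein length for the x-axis limit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_calls
#' @export
autoplot.binding_calls <- function(object, sequence_length = NULL, ...) {
  regions <- object$regions
  motifs <- object$motifs
  xmax <- if (!is.null(sequence_length)) sequence_length
          else max(regions$end, motifs$end, 1L)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = 1),
      fill = "darkseagreen3", colour = "grey30") +
    ggplot2::xlim(0, xmax) +
    ggplot2::labs(x = "residue", y = NULL,
                  title = "Candidate binding regions and surviving motifs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (nrow(motifs) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = motifs,
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   xend = (.data$start + .data$end) / 2,
                   y = 1, yend = 1.4, colour = .data$pattern_id),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
      ggplot2::labs(colour = "motif")
  }
  p
}

#' Write a binding call set to disk
#'
#' Emits the full call set as JSON (regions, surviving motifs,
#' non-canonical regions, audit log) plus human-readable TSVs of the
#' region and motif tables.
#'
#' @param calls A \code{binding_calls} object.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_binding_calls <- function(calls, dir) {
  stopifnot(inherits(calls, "binding_calls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regions <- dplyr::mutate(
    calls$regions,
    fragments = vapply(.data$fragments, paste, character(1), collapse = ","))
  readr::write_tsv(regions, file.path(dir, "regions.tsv"))
  readr::write_tsv(calls$motifs, file.path(dir, "motifs.tsv"))
  noncanon <- dplyr::mutate(
    calls$noncanonical_regions,
    fragments = vapply(.data$fragments, paste, character(1), collapse = ","))
  jsonlite::write_json(
    list(regions = regions, candidate_motifs = calls$motifs,
         noncanonical_regions = noncanon, audit_log = calls$audit),
    file.path(dir, "binding_calls.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
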