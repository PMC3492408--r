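# Packaged observation tables for the RyR1 photoaffinity-labeling
# analysis: everything the published account states in text or table form
# (fragment reads, apparent and calculated masses, label flags, parentage,
# membrane topology, mutagenesis exclusions). These are observations, not
# derived results; the pipeline recomputes everything downstream of them.

fixture_path <- function(name) {
  system.file("extdata", name, package = "nbsmapr", mustWork = TRUE)
}

#' Published RyR1 tryptic fragment observations
#'
#' The table of gel-observed tryptic fragments of RyR1: apparent SDS-PAGE
#' mass, Edman N-terminal read (with ambiguity notation, 'ND' = blocked
#' N-terminus), streptavidin label flag, proteolytic parentage, and --
#' where published -- the assigned sequence span (used to pin assignments
#' the way the original analysis disambiguated against previously
#' characterised digests). Fragments 12 and 14 are known only by
#' parentage and label status; their spans are NA.
#'
#' @return Tibble with columns \code{fragment_id}, \code{apparent_kda},
#'   \code{nterm_read}, \code{labeled}, \code{parent_id},
#'   \code{known_start}, \code{known_end}.
#' @export
ryr1_fragments <- function() {
  readr::read_tsv(fixture_path("ryr1_tryptic_fragments.tsv"),
                  na = "NA",
                  col_types = readr::cols(
                    fragment_id = readr::col_character(),
                    apparent_kda = readr::col_double(),
                    nterm_read = readr::col_character(),
                    labeled = readr::col_logical(),
                    parent_id = readr::col_character(),
                    known_start = readr::col_integer(),
                    known_end = readr::col_integer()))
}

#' Published RyR1 membrane topology intervals
#'
#' The predicted transmembrane region (residues 3985-4937) with the
#' luminal loop covering the consensus motif at 4602-4607. Positions not
#' covered by an interval are cytoplasmic.
#'
#' @return Tibble \code{start}, \code{end}, \code{compartment}.
#' @export
ryr1_topology <- function() {
  readr::read_tsv(fixture_path("ryr1_topology.tsv"),
                  col_types = readr::cols(
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    compartment = readr::col_character()))
}

#' Motif spans excluded by prior mutagenesis
#'
#' Consensus-motif spans ruled out as ATP-binding sites by earlier
#' alanine-scanning mutagenesis work: 2369-2377, 2370-2375 and 3937-3940.
#'
#' @return Tibble \code{start}, \code{end}, \code{reason}.
#' @export
ryr1_exclusions <- function() {
  readr::read_tsv(fixture_path("ryr1_motif_exclusions.tsv"),
                  col_types = readr::cols(
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    reason = readr::col_character()))
}
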