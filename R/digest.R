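#' Predict protease cleavage sites
#'
#' For trypsin the standard Keil rule is applied: cleave C-terminal to K or
#' R except when the next residue is proline. A cut at position i separates
#' residues i and i+1; the terminal residue never yields a cut.
#'
#' The rule table is internal but pluggable: \code{rule} selects an entry
#' in [cleavage_rules()], so alternative specificities can be added without
#' touching the digestion code.
#'
#' @param sequence Sequence tibble row from [read_fasta()] or a residue
#'   string.
#' @param rule Protease rule id; currently \code{"trypsin"}.
#' @return Integer vector of cut positions, strictly ascending, each in
#'   \code{[1, length - 1]}.
#' @export
#' @examples
#' cleavage_sites("AKPGRG")  # K2 blocked by P3; cut after R5 only
cleavage_sites <- function(sequence, rule = "trypsin") {
  residues <- as_residue_string(sequence)
  rules <- cleavage_rules()
  if (!rule %in% names(rules)) {
    stop("cleavage_sites(): unknown rule '", rule, "'; available: ",
         paste(names(rules), collapse = ", "), call. = FALSE)
  }
  r <- rules[[rule]]
  n <- nchar(residues)
  if (n < 2L) return(integer(0))
  aa <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- which(aa[-n] %in% r$after & !aa[-1] %in% r$not_before)
  as.integer(idx)
}

#' Protease rule table
#'
#' @return Named list of rules; each rule has \code{after} (residues cut
#'   C-terminal to) and \code{not_before} (residues blocking the cut when
#'   they follow).
#' @export
cleavage_rules <- function() {
  list(trypsin = list(after = c("K", "R"), not_before = "P"))
}

#' Complete in-silico digest
#'
#' Cuts at every predicted site, yielding fragments that partition the
#' sequence. This is the generative primitive used by the simulator; real
#' limited proteolysis is represented downstream by admitting any span
#' whose boundaries are cleavage sites or protein termini.
#'
#' @param sequence Sequence tibble row or residue string.
#' @param sites Cut positions, as from [cleavage_sites()]; computed from
#'   \code{rule} when omitted.
#' @param rule Protease rule id used when \code{sites} is missing.
#' @param table Mass table for calculated masses.
#' @return Tibble of fragments in order: \code{start}, \code{end},
#'   \code{calc_mass_da}, \code{calc_kda}.
#' @export
#' @examples
#' digest_fragments("AKPGRG")
digest_fragments <- function(sequence, sites = NULL, rule = "trypsin",
                             table = aa_mass_table()) {
  residues <- as_residue_string(sequence)
  n <- nchar(residues)
  if (is.null(sites)) sites <- cleavage_sites(residues, rule)
  if (length(sites)) {
    stopifnot(all(diff(sites) > 0), all(sites >= 1L), all(sites < n))
  }
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  mass <- vapply(seq_along(starts), function(i) {
    segment_mass(residues, starts[i], ends[i], table = table)
  }, numeric(1))
  tibble::tibble(start = starts, end = ends,
                 calc_mass_da = mass, calc_kda = round_kda(mass))
}
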