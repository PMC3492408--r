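#' Average amino-acid residue mass table
#'
#' Returns the table of average residue masses (Expasy convention) used for
#' all peptide-mass arithmetic in the package. Average rather than
#' monoisotopic masses are used throughout: the fragments handled here are
#' tens to hundreds of kilodaltons, where gel-derived masses follow the
#' average-mass scale.
#'
#' The table ships as a plain TSV under \code{inst/extdata} so the mass
#' convention is auditable and versioned with the package.
#'
#' @return A tibble with columns \code{residue} (one-letter code) and
#'   \code{mass_da} (average residue mass, Da).
#' @export
#' @examples
#' aa_mass_table()
aa_mass_table <- function() {
  path <- system.file("extdata", "aa_average_masses.tsv", package = "nbsmapr",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    residue = readr::col_character(),
    mass_da = readr::col_double()
  ))
}

#' Mass of one water molecule, Da (average)
#' @export
water_mass <- 18.01528

# internal: named numeric lookup vector from the table
mass_lookup <- function(table = aa_mass_table()) {
  stats::setNames(table$mass_da, table$residue)
}

#' Average mass of a peptide segment
#'
#' Sums average residue masses over a 1-based inclusive span of a protein
#' sequence and adds one water, giving the mass of the excised peptide
#' (not a bare residue sum).
#'
#' @param residues Character scalar: the full protein residue string, or a
#'   one-row sequence tibble as returned by [read_fasta()].
#' @param start,end 1-based inclusive span; defaults cover the whole
#'   sequence.
#' @param table Mass table (see [aa_mass_table()]).
#' @param x_fallback Mass (Da) to use for 'X' (unknown) residues. The
#'   default \code{NULL} makes an 'X' inside the span an error, preventing
#'   silent mass bias; pass e.g. the mean residue mass to override.
#' @return Peptide mass in Da.
#' @export
#' @examples
#' segment_mass("GG")           # 2 glycines + water
#' segment_mass("AKPGRG", 1, 5)
segment_mass <- function(residues, start = 1L, end = NULL,
                         table = aa_mass_table(), x_fallback = NULL) {
  residues <- as_residue_string(residues)
  n <- nchar(residues)
  if (is.null(end)) end <- n
  if (!(start >= 1 && start <= end && end <= n)) {
    stop("segment_mass(): span ", start, "-", end,
         " out of range for sequence of length ", n, call. = FALSE)
  }
  aa <- strsplit(substr(residues, start, end), "", fixed = TRUE)[[1]]
  lut <- mass_lookup(table)
  m <- lut[aa]
  if (anyNA(m)) {
    bad <- aa[is.na(m)]
    if (all(bad == "X") && !is.null(x_fallback)) {
      m[is.na(m)] <- x_fallback
    } else {
      stop("segment_mass(): residue(s) without a mass in span ",
           start, "-", end, ": ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
  }
  sum(m) + water_mass
}

#' Round a mass in Da to integer kDa, half-up
#'
#' Gel and table molecular weights are conventionally printed as integer
#' kDa; this uses the half-up rule (99500 Da -> 100 kDa), not banker's
#' rounding.
#'
#' @param mass_da Non-negative mass in Da (vectorised).
#' @return Integer kDa.
#' @export
round_kda <- function(mass_da) {
  if (any(mass_da < 0)) stop("round_kda(): negative mass", call. = FALSE)
  as.integer(floor(mass_da / 1000 + 0.5))
}

# accept either a plain string or a one-row tibble from read_fasta()
as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L || !"residues" %in% names(x)) {
      stop("expected a single-row sequence tibble with a 'residues' column",
           call. = FALSE)
    }
    x <- x$residues
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("expected a single residue string", call. = FALSE)
  }
  x
}
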