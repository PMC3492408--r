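# Independent oracles and tiny generators used across the suite.

# random residue string (20 standard letters, uniform)
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# brute-force per-window motif matcher, independent of the scanner's regex
# machinery: walks every window and compares position sets element-wise
brute_force_scan <- function(residues, pattern) {
  aa <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- pattern$length
  n <- length(aa)
  if (n < L) return(integer(0))
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hits <- integer(0)
  for (s in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      e <- pattern$elements[[k]]
      r <- aa[s + k - 1L]
      allowed <- if (length(e) == 1L && is.na(e)) standard else e
      if (!r %in% allowed) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# per-residue mass sum, independent of segment_mass's lookup path
brute_force_mass <- function(residues, start, end) {
  lut <- with(aa_mass_table(), stats::setNames(mass_da, residue))
  total <- 0
  for (p in start:end) total <- total + lut[[substr(residues, p, p)]]
  total + water_mass
}

# expected segment masses used in more than one file
published_fragment_masses <- function() {
  tibble::tibble(
    fragment_id = c("8", "11", "15", "1", "7", "6", "3"),
    start = c(427L, 4476L, 2402L, 3120L, 1509L, 3631L, 1L),
    end = c(1302L, 5037L, 2795L, 4673L, 2399L, 4673L, 1302L),
    kda = c(99L, 64L, 45L, 176L, 102L, 118L, 148L)
  )
}
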