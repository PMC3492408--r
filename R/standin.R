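# Construction of the synthetic RyR1 stand-in sequence.
#
# The real rabbit RyR1 sequence (Swiss-Prot P11716) is not redistributed
# with the package. Instead a SYNTHETIC stand-in of the same length (5037
# residues) is constructed to satisfy every published constraint the
# pipeline consumes, so that the full inference is exercisable offline:
#   * the six Edman N-terminal reads at their published start coordinates;
#   * tryptic junctions (K/R not followed by P) at every published
#     fragment boundary;
#   * per-fragment average masses reproducing the published integer-kDa
#     calculated-mass column;
#   * the 16 published nucleotide-binding consensus motif instances at
#     their published spans;
#   * no other motif hits inside the cytoplasmic parts of the three
#     candidate regions, so the final motif call set is exactly the
#     published one.
# Everything else is random background. Results on this sequence validate
# the machinery against the published coordinate arithmetic; they are not
# statements about the real protein. Supply a real P11716 FASTA via
# read_fasta() to reproduce the analysis on the true sequence.

standin_constants <- function() {
  list(
    length = 5037L,
    reads = tibble::tibble(
      start = c(427L, 1509L, 2402L, 3120L, 3631L, 4476L),
      # 'S' stands in for the unidentified cycle (X) of the 3631 read
      seq = c("GSGPPAGPAL", "ISHTDLVIG", "RREHFGEEPP", "TQVKGVGQN",
              "AVVASFRMTP", "KLGVDGEEEE")
    ),
    junctions = c(426L, 1302L, 1508L, 2399L, 2401L, 2795L, 3119L, 3630L,
                  4475L, 4673L),
    after_junction_free = c(1303L, 2400L, 2796L, 4674L),  # forced non-P
    walker_a = c(2L, 699L, 701L, 1195L, 2264L, 2370L, 4449L, 4452L, 4602L),
    walker_b = c(1302L, 2126L, 2369L),
    groes = c(1081L, 2935L, 3503L, 3937L),
    # peptide-mass targets (Da, incl. one water) for the published
    # integer-kDa column; 1-426 and 3120-3630 are differences of published
    # values so the containing fragments also land on target
    mass_targets = tibble::tibble(
      start = c(1L, 427L, 1509L, 2402L, 3120L, 3631L),
      end = c(426L, 1302L, 2399L, 2795L, 3630L, 4673L),
      target = c(49000 + water_mass, 99000, 102000, 45000,
                 58000 + water_mass, 118000)
    ),
    # cytoplasmic stretches of the three candidate regions: the published
    # motif call must be exactly reproduced inside these
    zones = tibble::tibble(start = c(427L, 2402L, 4938L),
                           end = c(1302L, 2795L, 5037L)),
    wanted = tibble::tibble(
      pattern_id = c("WALKER_A", "WALKER_A", "GROES", "WALKER_A"),
      start = c(699L, 701L, 1081L, 1195L)
    ),
    # mass-tuning palette: no G/P/K/R/L/Y, so tuning can never create a
    # cleavage site, block one, or complete a motif anchor
    palette = c("A", "S", "T", "V", "I", "N", "D", "Q", "E", "M", "F",
                "W", "H", "C")
  )
}

plant_residue <- function(aa, fixed, pos, residue, allowed = residue) {
  if (fixed[pos] && !aa[pos] %in% allowed) {
    stop("stand-in construction: collision at position ", pos,
         " (have ", aa[pos], ", need one of ",
         paste(allowed, collapse = "/"), ")", call. = FALSE)
  }
  if (!aa[pos] %in% allowed) aa[pos] <- residue
  fixed[pos] <- TRUE
  list(aa = aa, fixed = fixed)
}

tune_segment_mass <- function(aa, fixed, s, e, target, lut, palette,
                              tol = 30, max_iter = 20000L) {
  pal_mass <- lut[palette]
  repeat {
    cur <- sum(lut[aa[s:e]]) + water_mass
    delta <- target - cur
    if (abs(delta) <= tol) break
    free <- which(!fixed[s:e]) + s - 1L
    if (length(free) == 0L) stop("stand-in construction: no free positions to tune ",
                                 s, "-", e, call. = FALSE)
    improved <- FALSE
    for (p in sample(free, min(length(free), 200L))) {
      m0 <- lut[[aa[p]]]
      gain <- pal_mass - m0
      best <- which.min(abs(delta - gain))
      if (abs(delta - gain[best]) < abs(delta) - 1e-9) {
        aa[p] <- palette[best]
        improved <- TRUE
        break
      }
    }
    if (!improved) break  # as close as the palette allows
    max_iter <- max_iter - 1L
    if (max_iter <= 0L) break
  }
  aa
}

repair_zone_hits <- function(aa, fixed, const) {
  residues <- paste(aa, collapse = "")
  hits <- scan_motifs(residues, builtin_patterns())
  pats <- builtin_patterns()
  changed <- FALSE
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    in_zone <- any(const$zones$start <= h$start & h$end <= const$zones$end)
    if (!in_zone) next
    wanted <- any(const$wanted$pattern_id == h$pattern_id &
                    const$wanted$start == h$start)
    if (wanted) next
    pat <- pats[[h$pattern_id]]
    done <- FALSE
    for (k in seq_len(pat$length)) {
      e <- pat$elements[[k]]
      if (length(e) == 1L && is.na(e)) next  # wildcard: unbreakable
      p <- h$start + k - 1L
      if (fixed[p]) next
      repl <- setdiff(const$palette, e)[1]
      aa[p] <- repl
      fixed[p] <- TRUE  # lock so later tuning cannot rebuild the hit
      done <- TRUE
      changed <- TRUE
      break
    }
    if (!done) {
      stop("stand-in construction: cannot break unwanted hit ",
           h$pattern_id, " ", h$start, "-", h$end, call. = FALSE)
    }
  }
  list(aa = aa, fixed = fixed, changed = changed)
}

#' Build the synthetic RyR1 stand-in sequence
#'
#' Constructs, deterministically from a seed, a 5037-residue synthetic
#' protein satisfying every published constraint of the rabbit RyR1
#' photoaffinity-labeling analysis (see the comment block in the source
#' and the package vignette): Edman reads at their published coordinates,
#' tryptic junctions at fragment boundaries, fragment masses matching the
#' published calculated-kDa column, the 16 consensus-motif instances at
#' their published spans, and no stray motifs inside the cytoplasmic
#' survival zones of the candidate regions. The shipped copy is at
#' \code{system.file("extdata", "ryr1_p11716_synthetic.fasta",
#' package = "nbsmapr")}; see [ryr1_standin()].
#'
#' This is a \strong{synthetic} sequence: it validates coordinate
#' arithmetic and inference logic, not biology on the real protein.
#'
#' @param seed Integer seed for the random background.
#' @return Sequence tibble (\code{id}, \code{residues}, \code{length})
#'   with id \code{"RYR1_SYNTHETIC_STANDIN"}.
#' @export
build_reference_standin <- function(seed = 11716L) {
  const <- standin_constants()
  lut <- mass_lookup()
  with_seed_local(seed, {
    freqs <- residue_frequencies("swissprot")
    aa <- sample(names(freqs), const$length, replace = TRUE, prob = freqs)
    fixed <- logical(const$length)

    # Edman reads
    for (i in seq_len(nrow(const$reads))) {
      chars <- strsplit(const$reads$seq[i], "", fixed = TRUE)[[1]]
      for (k in seq_along(chars)) {
        p <- const$reads$start[i] + k - 1L
        r <- plant_residue(aa, fixed, p, chars[k])
        aa <- r$aa; fixed <- r$fixed
      }
    }
    # tryptic junctions and their non-P followers
    for (p in const$junctions) {
      r <- plant_residue(aa, fixed, p, "K", allowed = c("K", "R"))
      aa <- r$aa; fixed <- r$fixed
    }
    for (p in const$after_junction_free) {
      r <- plant_residue(aa, fixed, p, "A")
      aa <- r$aa; fixed <- r$fixed
    }
    # consensus-motif plants
    for (s in const$walker_a) {
      for (off in c(0L, 2L, 5L)) {
        r <- plant_residue(aa, fixed, s + off, "G")
        aa <- r$aa; fixed <- r$fixed
      }
    }
    for (s in const$walker_b) {
      r <- plant_residue(aa, fixed, s, "K", allowed = c("K", "R"))
      aa <- r$aa; fixed <- r$fixed
      r <- plant_residue(aa, fixed, s + 4L, "G"); aa <- r$aa; fixed <- r$fixed
      r <- plant_residue(aa, fixed, s + 8L, "L"); aa <- r$aa; fixed <- r$fixed
    }
    for (s in const$groes) {
      r <- plant_residue(aa, fixed, s, "Y"); aa <- r$aa; fixed <- r$fixed
      r <- plant_residue(aa, fixed, s + 1L, "S", allowed = c("G", "A", "S", "T"))
      aa <- r$aa; fixed <- r$fixed
      r <- plant_residue(aa, fixed, s + 2L, "V", allowed = c("V", "G"))
      aa <- r$aa; fixed <- r$fixed
      r <- plant_residue(aa, fixed, s + 3L, "T",
                         allowed = c("K", "T", "Q", "S", "N"))
      aa <- r$aa; fixed <- r$fixed
    }

    # fixed point: purge stray zone hits, then retune masses (repairs are
    # locked, tuning uses an anchor-free palette, so this converges)
    for (iter in 1:30) {
      rep <- repair_zone_hits(aa, fixed, const)
      aa <- rep$aa; fixed <- rep$fixed
      for (i in seq_len(nrow(const$mass_targets))) {
        aa <- tune_segment_mass(aa, fixed, const$mass_targets$start[i],
                                const$mass_targets$end[i],
                                const$mass_targets$target[i],
                                lut, const$palette)
      }
      # C-terminal tail: target chosen so 4476-5037 lands on the
      # published 64 kDa given the (already tuned) 4476-4673 overlap
      m_overlap <- sum(lut[aa[4476:4673]]) + water_mass
      tail_target <- 64000 - m_overlap + water_mass
      aa <- tune_segment_mass(aa, fixed, 4674L, 5037L, tail_target,
                              lut, const$palette)
      rep2 <- repair_zone_hits(aa, fixed, const)
      aa <- rep2$aa; fixed <- rep2$fixed
      if (!rep2$changed) break
    }
    tibble::tibble(id = "RYR1_SYNTHETIC_STANDIN",
                   residues = paste(aa, collapse = ""),
                   length = const$length)
  })
}

#' Packaged synthetic RyR1 stand-in sequence
#'
#' Reads the shipped copy of the synthetic stand-in built by
#' [build_reference_standin()] (see that help page for what it does and
#' does not represent).
#'
#' @return Sequence tibble as from [read_fasta()].
#' @export
ryr1_standin <- function() {
  read_fasta(system.file("extdata", "ryr1_p11716_synthetic.fasta",
                         package = "nbsmapr", mustWork = TRUE))
}
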