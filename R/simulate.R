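# run code with a deterministic RNG state, restoring the caller's state
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Amino-acid background frequencies
#'
#' \code{"swissprot"} approximates the residue composition of the known
#' protein universe; \code{"uniform"} gives each of the 20 standard
#' residues probability 1/20.
#'
#' @param composition \code{"swissprot"} or \code{"uniform"}.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
residue_frequencies <- function(composition = c("swissprot", "uniform")) {
  composition <- match.arg(composition)
  if (composition == "uniform") {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    return(stats::setNames(rep(1 / 20, 20), aa))
  }
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  f / sum(f)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the study conditions the rest of the package is validated under:
#' multiplicative lognormal gel-mass noise with sigma 0.05 (SDS-PAGE
#' apparent-vs-calculated discrepancies are proportional, a few to ~9
#' percent), 10-cycle Edman reads, and competition curves of 8 log-spaced
#' ATP concentrations read in 3 replicates with additive noise sigma 0.05.
#' The default true IC50 of 0.6 mM is the SR-membrane condition; use
#' 0.95 mM with concentrations up to 50 mM for the purified-receptor
#' condition.
#'
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param length Protein length (residues).
#' @param composition Background residue composition
#'   (see [residue_frequencies()]), or a named frequency vector.
#' @param motifs Tibble of planted motif instances: \code{pattern_id}
#'   (key into \code{patterns}), \code{position} (1-based start).
#' @param patterns Named list of \code{motif_pattern}s the plants refer to.
#' @param sites Integer positions of planted binding (label) sites.
#' @param n_fragments Number of observed partial-digest fragments to draw.
#' @param mass_sigma Sigma of multiplicative lognormal gel-mass noise.
#' @param read_length Edman read length (cycles).
#' @param miscall_rate Per-cycle probability that a call becomes ambiguous
#'   ('X' or a parenthesised low-confidence call).
#' @param label_fn_rate Probability that a site-containing fragment is
#'   observed unlabeled (label false negative).
#' @param ic50_mM True IC50 of the simulated competition curve.
#' @param hill True Hill slope.
#' @param concentrations Competitor concentrations, mM.
#' @param curve_sigma Additive Gaussian noise sigma on the normalised
#'   response.
#' @param replicates Curve replicates.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       length = 2000L,
                       composition = "swissprot",
                       motifs = tibble::tibble(pattern_id = character(),
                                               position = integer()),
                       patterns = builtin_patterns(),
                       sites = integer(0),
                       n_fragments = 12L,
                       mass_sigma = 0.05,
                       read_length = 10L,
                       miscall_rate = 0.05,
                       label_fn_rate = 0,
                       ic50_mM = 0.6,
                       hill = 1,
                       concentrations = 10^seq(-2, 1, length.out = 8),
                       curve_sigma = 0.05,
                       replicates = 3L) {
  freqs <- if (is.character(composition)) residue_frequencies(composition)
           else composition / sum(composition)
  stopifnot(length >= 1L,
            mass_sigma >= 0, curve_sigma >= 0,
            miscall_rate >= 0, miscall_rate <= 1,
            label_fn_rate >= 0, label_fn_rate <= 1,
            all(sites >= 1L & sites <= length),
            ic50_mM > 0, hill > 0,
            all(concentrations >= 0))
  structure(
    list(seed = as.integer(seed), length = as.integer(length),
         freqs = freqs, motifs = motifs, patterns = patterns,
         sites = as.integer(sites), n_fragments = as.integer(n_fragments),
         mass_sigma = mass_sigma, read_length = as.integer(read_length),
         miscall_rate = miscall_rate, label_fn_rate = label_fn_rate,
         ic50_mM = ic50_mM, hill = hill, concentrations = concentrations,
         curve_sigma = curve_sigma, replicates = as.integer(replicates)),
    class = "sim_config"
  )
}

#' Simulate a protein sequence with planted motifs
#'
#' Draws a random sequence from the configured background composition and
#' overwrites residues at planted motif positions: fixed pattern positions
#' get the required residue (first class member for classes), wildcard
#' positions keep the background draw. Planted instances are verified to
#' match their pattern; two plants demanding different residues at one
#' position is a collision error.
#'
#' @param config A [sim_config()].
#' @return List with \code{sequence} (tibble as from [read_fasta()]) and
#'   \code{truth} (list: \code{motifs} tibble with spans, \code{sites}).
#' @export
simulate_protein <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed, {
    aa <- sample(names(config$freqs), config$length, replace = TRUE,
                 prob = config$freqs)
    owner <- rep(NA_character_, config$length)
    m <- config$motifs
    if (nrow(m) > 0L) {
      for (i in seq_len(nrow(m))) {
        pid <- m$pattern_id[i]
        pos <- m$position[i]
        pat <- config$patterns[[pid]]
        if (is.null(pat)) stop("simulate_protein(): unknown pattern_id '",
                               pid, "'", call. = FALSE)
        if (pos < 1L || pos + pat$length - 1L > config$length) {
          stop("simulate_protein(): plant at ", pos, " out of range",
               call. = FALSE)
        }
        for (k in seq_len(pat$length)) {
          e <- pat$elements[[k]]
          if (length(e) == 1L && is.na(e)) next  # wildcard: keep background
          p <- pos + k - 1L
          want <- e[1]
          if (!is.na(owner[p]) && aa[p] != want && !aa[p] %in% e) {
            stop("simulate_protein(): motif collision at position ", p,
                 " between plants '", owner[p], "' and '", pid, "'",
                 call. = FALSE)
          }
          if (!aa[p] %in% e) aa[p] <- want
          owner[p] <- pid
        }
      }
    }
    residues <- paste(aa, collapse = "")
    # verify each plant matches its pattern
    if (nrow(m) > 0L) {
      for (i in seq_len(nrow(m))) {
        pat <- config$patterns[[m$pattern_id[i]]]
        hits <- scan_motifs(residues, pat)
        if (!m$position[i] %in% hits$start) {
          stop("simulate_protein(): planted '", m$pattern_id[i], "' at ",
               m$position[i], " does not match after planting", call. = FALSE)
        }
      }
    }
    truth_motifs <- if (nrow(m) > 0L) {
      tibble::tibble(
        pattern_id = m$pattern_id,
        start = as.integer(m$position),
        end = as.integer(m$position) +
          vapply(m$pattern_id, function(p) config$patterns[[p]]$length,
                 integer(1)) - 1L)
    } else {
      tibble::tibble(pattern_id = character(), start = integer(),
                     end = integer())
    }
    list(
      sequence = tibble::tibble(id = paste0("sim_", config$seed),
                                residues = residues,
                                length = nchar(residues)),
      truth = list(motifs = truth_motifs, sites = config$sites)
    )
  })
}

#' Simulate observed partial-digest fragments
#'
#' Emulates the observation process of a limited proteolysis experiment:
#' fragment spans are drawn with boundaries at predicted cleavage sites or
#' protein termini; apparent gel mass is the calculated mass under
#' multiplicative lognormal noise; the Edman read is the true N-terminal
#' prefix with seeded miscalls turned into 'X' or parenthesised
#' low-confidence calls; the label flag is set when the span contains a
#' planted binding site, subject to a false-negative rate. Parentage is
#' emitted whenever one sampled span contains another (parent = the
#' smallest containing span).
#'
#' @param sequence Sequence tibble row or residue string (from
#'   [simulate_protein()]).
#' @param truth Truth list from [simulate_protein()] (uses \code{sites}).
#' @param config A [sim_config()].
#' @param rule Protease rule.
#' @return Tibble of observed fragments: \code{fragment_id},
#'   \code{apparent_kda}, \code{nterm_read}, \code{labeled},
#'   \code{parent_id}, plus ground-truth columns \code{true_start},
#'   \code{true_end}.
#' @export
simulate_observed_fragments <- function(sequence, truth, config,
                                        rule = "trypsin") {
  stopifnot(inherits(config, "sim_config"))
  residues <- as_residue_string(sequence)
  n <- nchar(residues)
  sites <- cleavage_sites(residues, rule)
  bounds <- c(0L, sites, n)  # a span runs (bounds[i]+1) .. bounds[j], i < j
  if (length(bounds) < 2L) stop("simulate_observed_fragments(): no admissible spans",
                                call. = FALSE)
  with_seed_local(config$seed + 1L, {
    k <- config$n_fragments
    i <- sample(seq_len(length(bounds) - 1L), k, replace = TRUE)
    j <- vapply(i, function(ii) {
      js <- seq(ii + 1L, length(bounds))
      js[sample.int(length(js), 1L)]
    }, integer(1))
    spans <- tibble::tibble(start = bounds[i] + 1L, end = bounds[j])
    spans <- dplyr::distinct(spans)
    lut <- mass_lookup()
    out <- purrr::map_dfr(seq_len(nrow(spans)), function(fi) {
      s <- spans$start[fi]; e <- spans$end[fi]
      calc <- segment_mass(residues, s, e)
      apparent <- calc / 1000 * exp(stats::rnorm(1, 0, config$mass_sigma))
      rl <- min(config$read_length, e - s + 1L)
      true_read <- strsplit(substr(residues, s, s + rl - 1L), "")[[1]]
      read <- vapply(true_read, function(r) {
        if (stats::runif(1) < config$miscall_rate) {
          if (stats::runif(1) < 0.5) "X" else paste0("(", r, ")")
        } else r
      }, character(1))
      contains_site <- any(truth$sites >= s & truth$sites <= e)
      labeled <- contains_site &&
        stats::runif(1) >= config$label_fn_rate
      tibble::tibble(
        fragment_id = paste0("F", fi),
        apparent_kda = apparent,
        nterm_read = paste(read, collapse = ""),
        labeled = labeled,
        true_start = s, true_end = e
      )
    })
    # parentage: smallest strictly containing sampled span
    out$parent_id <- vapply(seq_len(nrow(out)), function(fi) {
      s <- out$true_start[fi]; e <- out$true_end[fi]
      cont <- which(out$true_start <= s & out$true_end >= e &
                      (out$true_end - out$true_start > e - s))
      if (length(cont) == 0L) return(NA_character_)
      sizes <- out$true_end[cont] - out$true_start[cont]
      out$fragment_id[cont[which.min(sizes)]]
    }, character(1))
    dplyr::select(out, "fragment_id", "apparent_kda", "nterm_read",
                  "labeled", "parent_id", "true_start", "true_end")
  })
}

#' Simulate a competition-binding curve
#'
#' Generates \eqn{y = 1/(1 + (c/IC_{50})^h) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma)}, per concentration and replicate,
#' seeded from the configuration.
#'
#' @param config A [sim_config()] (uses \code{ic50_mM}, \code{hill},
#'   \code{concentrations}, \code{curve_sigma}, \code{replicates}).
#' @return List with \code{curve} (tibble \code{atp_mM}, \code{y},
#'   \code{replicate}) and \code{truth} (list \code{ic50_mM},
#'   \code{hill}).
#' @export
simulate_curve <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  conc <- config$concentrations
  if (length(unique(conc[conc > 0])) < 4L) {
    stop("simulate_curve(): need >= 4 distinct positive concentrations",
         call. = FALSE)
  }
  with_seed_local(config$seed + 2L, {
    grid <- tidyr::expand_grid(replicate = seq_len(config$replicates),
                               atp_mM = conc)
    mu <- 1 / (1 + (grid$atp_mM / config$ic50_mM)^config$hill)
    grid$y <- mu + stats::rnorm(nrow(grid), 0, config$curve_sigma)
    list(curve = dplyr::select(grid, "atp_mM", "y", "replicate"),
         truth = list(ic50_mM = config$ic50_mM, hill = config$hill))
  })
}
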