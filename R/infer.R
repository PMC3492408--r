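# Interval helpers on 1-based inclusive (start, end) tibbles. The spans
# involved are few (a dozen fragments), so plain vector arithmetic keeps
# the rule bookkeeping transparent.

interval_subtract <- function(start, end, sub_start, sub_end) {
  # subtract one interval from one interval; returns tibble of remainders
  if (sub_end < start || sub_start > end) {
    return(tibble::tibble(start = start, end = end))
  }
  out <- tibble::tibble(start = integer(), end = integer())
  if (sub_start > start) {
    out <- dplyr::bind_rows(out, tibble::tibble(start = start,
                                                end = sub_start - 1L))
  }
  if (sub_end < end) {
    out <- dplyr::bind_rows(out, tibble::tibble(start = sub_end + 1L,
                                                end = end))
  }
  out
}

merge_intervals <- function(df) {
  # merge overlapping intervals; supporting fragment ids are unioned
  if (nrow(df) == 0L) return(df)
  df <- dplyr::arrange(df, .data$start, .data$end)
  merged <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(merged)
    if (df$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], df$end[i])
      merged$fragments[[last]] <- sort(unique(c(merged$fragments[[last]],
                                                df$fragments[[i]])))
    } else {
      merged <- dplyr::bind_rows(merged, df[i, ])
    }
  }
  merged
}

audit_row <- function(rule, subject, detail) {
  tibble::tibble(rule = rule, subject = as.character(subject), detail = detail)
}

#' Refine labeled fragment spans into candidate binding regions
#'
#' The elimination/refinement inference at the heart of the package. Each
#' photoaffinity-labeled fragment supports the hypothesis that the label --
#' and hence the ligand-binding site -- lies within its span; unlabeled
#' fragments and proteolytic parentage narrow that support:
#'
#' \itemize{
#'   \item \strong{R1 (descend)}: if a labeled fragment has labeled
#'     proteolytic products, the region narrows to each deepest labeled
#'     descendant's span -- the label travelled into the product, so the
#'     precursor-only residues are not required for binding.
#'   \item \strong{R2 (subtract)}: spans of unlabeled descendants are
#'     subtracted -- a fragment observed without label cannot carry the
#'     site. A C-terminal ambiguity window \code{w} shrinks each
#'     subtracted span at its C-terminus first, because C-termini assigned
#'     by gel mass against clustered cleavage sites are uncertain.
#'   \item \strong{R3 (demote)}: a labeled fragment \emph{all} of whose
#'     direct products are unlabeled is demoted entirely -- if the label
#'     survives nowhere among the products, its original placement is
#'     suspect (it may sit on residues trimmed during further digestion).
#'     Controlled by \code{demote_on_unlabeled_products} since the
#'     underlying evidence is equivocal.
#'   \item \strong{R4 (merge)}: overlapping surviving regions are merged.
#' }
#'
#' @param fragments Tibble with \code{fragment_id}, \code{start},
#'   \code{end} (NA allowed for fragments known only by parentage),
#'   \code{labeled}, \code{parent_id}. Typically the output of
#'   [assign_fragments()].
#' @param w C-terminal ambiguity window (residues) applied to subtracted
#'   unlabeled spans; default 0.
#' @param demote_on_unlabeled_products Apply rule R3; default \code{TRUE}.
#' @return Tibble of candidate regions sorted by start: \code{start},
#'   \code{end}, \code{fragments} (list column of supporting fragment
#'   ids), with an \code{"audit"} attribute tibble logging every rule
#'   firing (\code{rule}, \code{subject}, \code{detail}).
#' @export
refine_regions <- function(fragments, w = 0L,
                           demote_on_unlabeled_products = TRUE) {
  stopifnot(all(c("fragment_id", "start", "end", "labeled") %in%
                  names(fragments)))
  frag <- tibble::as_tibble(fragments)
  frag$fragment_id <- as.character(frag$fragment_id)
  if (!"parent_id" %in% names(frag)) frag$parent_id <- NA_character_
  frag$parent_id <- as.character(frag$parent_id)
  if (anyDuplicated(frag$fragment_id)) {
    stop("refine_regions(): duplicated fragment_id", call. = FALSE)
  }
  # order-independence: canonicalise input order
  frag <- dplyr::arrange(frag, .data$fragment_id)

  ids <- frag$fragment_id
  parent <- stats::setNames(frag$parent_id, ids)
  span <- stats::setNames(lapply(seq_along(ids), function(i)
    c(frag$start[i], frag$end[i])), ids)
  labeled <- stats::setNames(frag$labeled, ids)

  # validate: acyclic parentage, children contained in parents
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(parent[[cur]]) && parent[[cur]] %in% ids) {
      if (cur %in% seen) stop("refine_regions(): cyclic derivation graph at '",
                              cur, "'", call. = FALSE)
      seen <- c(seen, cur)
      p <- parent[[cur]]
      cs <- span[[cur]]; ps <- span[[p]]
      if (!anyNA(cs) && !anyNA(ps) && (cs[1] < ps[1] || cs[2] > ps[2])) {
        stop("refine_regions(): fragment '", cur, "' (", cs[1], "-", cs[2],
             ") not contained in parent '", p, "' (", ps[1], "-", ps[2], ")",
             call. = FALSE)
      }
      cur <- p
    }
  }

  children_of <- function(id) ids[!is.na(parent[ids]) & parent[ids] == id]
  descendants_of <- function(id) {
    kids <- children_of(id)
    if (length(kids) == 0L) return(character(0))
    c(kids, unlist(lapply(kids, descendants_of), use.names = FALSE))
  }

  audit <- tibble::tibble(rule = character(), subject = character(),
                          detail = character())

  # R3: demotion (computed first so demoted fragments do not anchor R1)
  effective_labeled <- labeled
  if (demote_on_unlabeled_products) {
    for (id in ids[labeled %in% TRUE]) {
      kids <- children_of(id)
      if (length(kids) > 0L && all(!labeled[kids])) {
        effective_labeled[id] <- FALSE
        audit <- dplyr::bind_rows(audit, audit_row(
          "R3", id, paste0("demoted: all direct products (",
                           paste(kids, collapse = ", "), ") unlabeled")))
      }
    }
  }

  roots <- ids[is.na(parent[ids]) | !(parent[ids] %in% ids)]
  regions <- tibble::tibble(start = integer(), end = integer(),
                            fragments = list())

  for (root in roots) {
    if (!isTRUE(effective_labeled[[root]])) next
    if (anyNA(span[[root]])) next
    desc <- descendants_of(root)
    lab_desc <- desc[effective_labeled[desc] %in% TRUE &
                       !vapply(span[desc], anyNA, logical(1))]
    # deepest labeled descendants: labeled descendants none of whose own
    # descendants are labeled
    deepest <- lab_desc[vapply(lab_desc, function(d) {
      dd <- descendants_of(d)
      !any(effective_labeled[dd] %in% TRUE)
    }, logical(1))]
    if (length(deepest) > 0L) {
      pieces <- tibble::tibble(
        start = unname(vapply(deepest, function(d) as.integer(span[[d]][1]),
                              integer(1))),
        end = unname(vapply(deepest, function(d) as.integer(span[[d]][2]),
                            integer(1))),
        fragments = unname(lapply(deepest,
                                  function(d) sort(unique(c(root, d))))))
      for (d in deepest) {
        audit <- dplyr::bind_rows(audit, audit_row(
          "R1", root, paste0("narrowed to deepest labeled descendant '", d,
                             "': ", span[[d]][1], "-", span[[d]][2])))
      }
    } else {
      pieces <- tibble::tibble(start = as.integer(span[[root]][1]),
                               end = as.integer(span[[root]][2]),
                               fragments = list(root))
    }
    # R2: subtract unlabeled descendant spans (shrunk at C-terminus by w)
    unlab <- desc[labeled[desc] %in% FALSE &
                    !vapply(span[desc], anyNA, logical(1))]
    for (u in unlab) {
      us <- span[[u]][1]
      ue <- span[[u]][2] - as.integer(w)
      if (ue < us) next
      new_pieces <- pieces[0, ]
      changed <- FALSE
      for (i in seq_len(nrow(pieces))) {
        rem <- interval_subtract(pieces$start[i], pieces$end[i], us, ue)
        if (nrow(rem) != 1L || rem$start[1] != pieces$start[i] ||
            rem$end[1] != pieces$end[i]) changed <- TRUE
        if (nrow(rem) > 0L) {
          rem$fragments <- rep(pieces$fragments[i], nrow(rem))
          new_pieces <- dplyr::bind_rows(new_pieces, rem)
        }
      }
      pieces <- new_pieces
      if (changed) {
        audit <- dplyr::bind_rows(audit, audit_row(
          "R2", root, paste0("subtracted unlabeled fragment '", u, "' span ",
                             us, "-", ue,
                             if (w > 0) paste0(" (C-terminal window ", w, ")"))))
      }
    }
    regions <- dplyr::bind_rows(regions, pieces)
  }

  n_before <- nrow(regions)
  regions <- merge_intervals(regions)
  if (nrow(regions) < n_before) {
    audit <- dplyr::bind_rows(audit, audit_row(
      "R4", "", paste0("merged ", n_before, " overlapping region piece(s) into ",
                       nrow(regions))))
  }
  regions <- dplyr::arrange(regions, .data$start)
  attr(regions, "audit") <- audit
  regions
}

#' Filter motif hits through regions, topology and exclusions
#'
#' Combines the scanner's motif hits with the refined candidate regions,
#' a membrane-topology annotation and a list of excluded motif spans
#' (e.g. sites ruled out by prior mutagenesis) into a final call set:
#'
#' \itemize{
#'   \item a hit survives only if \emph{fully contained} in a candidate
#'     region (a motif straddling a region boundary is not supported by
#'     the labeling evidence);
#'   \item hits overlapping an exclusion span are dropped with the
#'     exclusion's reason;
#'   \item a hit must be entirely cytoplasmic: positions not covered by a
#'     topology interval default to cytoplasmic, but any overlap with a
#'     transmembrane or luminal interval disqualifies the hit, because
#'     only cytoplasmic sequence can form the cytosolically regulated
#'     nucleotide site.
#' }
#'
#' Regions left with no surviving motif become \emph{non-canonical}
#' candidate regions: the labeling supports binding there, but no known
#' consensus motif explains it.
#'
#' @param hits Motif hit tibble from [scan_motifs()].
#' @param regions Candidate region tibble from [refine_regions()].
#' @param topology Optional tibble \code{start}, \code{end},
#'   \code{compartment} (\code{"cytoplasmic"}, \code{"transmembrane"},
#'   \code{"luminal"}); non-overlapping.
#' @param exclusions Optional tibble \code{start}, \code{end},
#'   \code{reason}.
#' @return An object of class \code{binding_calls}: a list with
#'   \code{regions}, \code{motifs} (surviving hits plus \code{region_start},
#'   \code{region_end}), \code{noncanonical_regions}, and \code{audit}
#'   (one row per rule firing, including every exclusion with its rule).
#' @export
filter_motifs <- function(hits, regions, topology = NULL, exclusions = NULL) {
  audit <- attr(regions, "audit")
  if (is.null(audit)) audit <- tibble::tibble(rule = character(),
                                              subject = character(),
                                              detail = character())
  if (!is.null(topology) && nrow(topology) > 1L) {
    t2 <- dplyr::arrange(topology, .data$start)
    if (any(t2$start[-1] <= t2$end[-nrow(t2)])) {
      stop("filter_motifs(): overlapping topology intervals", call. = FALSE)
    }
  }
  noncyto <- if (is.null(topology)) NULL else
    dplyr::filter(topology, .data$compartment != "cytoplasmic")

  keep <- logical(nrow(hits))
  if (nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      tag <- paste0(h$pattern_id, " ", h$start, "-", h$end)
      ri <- which(regions$start <= h$start & h$end <= regions$end)
      if (length(ri) == 0L) {
        audit <- dplyr::bind_rows(audit, audit_row(
          "containment", tag, "not contained in any candidate region"))
        next
      }
      if (!is.null(exclusions) && nrow(exclusions) > 0L) {
        ov <- which(exclusions$start <= h$end & h$start <= exclusions$end)
        if (length(ov) > 0L) {
          audit <- dplyr::bind_rows(audit, audit_row(
            "exclusion", tag,
            paste0("overlaps excluded span ", exclusions$start[ov[1]], "-",
                   exclusions$end[ov[1]], " (", exclusions$reason[ov[1]], ")")))
          next
        }
      }
      if (!is.null(noncyto) && nrow(noncyto) > 0L) {
        ov <- which(noncyto$start <= h$end & h$start <= noncyto$end)
        if (length(ov) > 0L) {
          audit <- dplyr::bind_rows(audit, audit_row(
            "topology", tag,
            paste0("not fully cytoplasmic: overlaps ",
                   noncyto$compartment[ov[1]], " segment ",
                   noncyto$start[ov[1]], "-", noncyto$end[ov[1]])))
          next
        }
      }
      keep[i] <- TRUE
    }
  }

  motifs <- hits[keep, , drop = FALSE]
  if (nrow(motifs) > 0L) {
    ridx <- vapply(seq_len(nrow(motifs)), function(i) {
      which(regions$start <= motifs$start[i] &
              motifs$end[i] <= regions$end)[1]
    }, integer(1))
    motifs$region_start <- regions$start[ridx]
    motifs$region_end <- regions$end[ridx]
  } else {
    motifs$region_start <- integer(0)
    motifs$region_end <- integer(0)
  }

  has_motif <- vapply(seq_len(nrow(regions)), function(i) {
    any(motifs$start >= regions$start[i] & motifs$end <= regions$end[i])
  }, logical(1))
  noncanon <- regions[!has_motif, , drop = FALSE]
  attr(noncanon, "audit") <- NULL

  structure(
    list(regions = regions, motifs = motifs,
         noncanonical_regions = noncanon, audit = audit),
    class = "binding_calls"
  )
}

#' @export
print.binding_calls <- function(x, ...) {
  cat("<binding_calls>\n")
  cat("Candidate regions (", nrow(x$regions), "):\n", sep = "")
  for (i in seq_len(nrow(x$regions))) {
    cat("  ", x$regions$start[i], "-", x$regions$end[i],
        "  [fragments: ", paste(x$regions$fragments[[i]], collapse = ", "),
        "]\n", sep = "")
  }
  cat("Surviving candidate motifs (", nrow(x$motifs), "):\n", sep = "")
  for (i in seq_len(nrow(x$motifs))) {
    cat("  ", x$motifs$pattern_id[i], " ", x$motifs$start[i], "-",
        x$motifs$end[i], " (", x$motifs$matched[i], ")\n", sep = "")
  }
  if (nrow(x$noncanonical_regions) > 0L) {
    cat("Non-canonical regions (labeled, no surviving motif):\n")
    for (i in seq_len(nrow(x$noncanonical_regions))) {
      cat("  ", x$noncanonical_regions$start[i], "-",
          x$noncanonical_regions$end[i], "\n", sep = "")
    }
  }
  cat("Audit log:", nrow(x$audit), "rule firing(s)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the surviving candidate motifs of a binding call set
#' @param x A \code{binding_calls} object.
#' @param ... Unused.
#' @return The surviving-motif tibble.
#' @method tidy binding_calls
#' @export
tidy.binding_calls <- function(x, ...) x$motifs

#' One-row summary of a binding call set
#' @param x A \code{binding_calls} object.
#' @param ... Unused.
#' @return Tibble with counts of regions, motifs, non-canonical regions
#'   and audit entries.
#' @method glance binding_calls
#' @export
glance.binding_calls <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_motifs = nrow(x$motifs),
    n_noncanonical = nrow(x$noncanonical_regions),
    n_audit = nrow(x$audit)
  )
}
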