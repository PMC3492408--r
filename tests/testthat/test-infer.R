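paper_fragments <- function() {
  assign_fragments(ryr1_standin(), ryr1_fragments())
}

test_that("refinement of the published fragment set yields three regions", {
  regions <- refine_regions(paper_fragments())
  expect_identical(regions$start, c(427L, 2402L, 4476L))
  expect_identical(regions$end, c(1302L, 2795L, 5037L))
  audit <- attr(regions, "audit")
  # fragment 7 demoted via its unlabeled products 12 and 14
  expect_true(any(audit$rule == "R3" & audit$subject == "7"))
  # unlabeled fragment 2 eliminated the 3120-4475 stretch
  expect_true(any(audit$rule == "R2" & grepl("3120-4475", audit$detail)))
})

test_that("refinement base cases: identity, containment, demotion off", {
  lone <- tibble::tibble(fragment_id = "a", start = 10L, end = 50L,
                         labeled = TRUE, parent_id = NA_character_)
  r <- refine_regions(lone)
  expect_identical(r$start, 10L)
  expect_identical(r$end, 50L)

  pair <- tibble::tibble(fragment_id = c("p", "c"),
                         start = c(1L, 1L), end = c(100L, 100L),
                         labeled = c(TRUE, TRUE),
                         parent_id = c(NA, "p"))
  r2 <- refine_regions(pair)
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$end, 100L)

  # all products unlabeled: demoted by default, kept when the flag is off
  trio <- tibble::tibble(fragment_id = c("p", "c1", "c2"),
                         start = c(1L, 1L, 60L), end = c(100L, 40L, 100L),
                         labeled = c(TRUE, FALSE, FALSE),
                         parent_id = c(NA, "p", "p"))
  expect_identical(nrow(refine_regions(trio)), 0L)
  kept <- refine_regions(trio, demote_on_unlabeled_products = FALSE)
  expect_identical(kept$start, 41L)  # 1-40 and 60-100 subtracted
  expect_identical(kept$end, 59L)
})

test_that("C-terminal ambiguity window shrinks subtracted spans", {
  trio <- tibble::tibble(fragment_id = c("p", "u"),
                         start = c(1L, 1L), end = c(100L, 40L),
                         labeled = c(TRUE, FALSE),
                         parent_id = c(NA, "p"))
  expect_identical(
    refine_regions(trio, demote_on_unlabeled_products = FALSE)$start, 41L)
  withw <- refine_regions(trio, w = 20L,
                          demote_on_unlabeled_products = FALSE)
  expect_identical(withw$start, 21L)  # last 20 residues of 'u' spared
})

test_that("refinement rejects malformed derivation graphs", {
  cyc <- tibble::tibble(fragment_id = c("a", "b"),
                        start = c(1L, 1L), end = c(50L, 50L),
                        labeled = c(TRUE, TRUE), parent_id = c("b", "a"))
  expect_error(refine_regions(cyc), "cyclic")
  esc <- tibble::tibble(fragment_id = c("p", "c"),
                        start = c(10L, 5L), end = c(50L, 20L),
                        labeled = c(TRUE, TRUE), parent_id = c(NA, "p"))
  expect_error(refine_regions(esc), "not contained")
})

test_that("refinement output is independent of fragment input order", {
  frag <- paper_fragments()
  set.seed(5)
  for (i in 1:5) {
    shuffled <- frag[sample(nrow(frag)), ]
    expect_identical(refine_regions(shuffled)[, c("start", "end")],
                     refine_regions(frag)[, c("start", "end")])
  }
})

test_that("full filtering reproduces the published motif call set", {
  seqs <- ryr1_standin()
  calls <- call_binding_regions(seqs, ryr1_fragments(),
                                topology = ryr1_topology(),
                                exclusions = ryr1_exclusions())
  expect_identical(calls$motifs$start, c(699L, 701L, 1081L, 1195L))
  expect_identical(calls$motifs$end, c(704L, 706L, 1084L, 1200L))
  # the luminal motif is excluded by topology, not containment
  expect_true(any(calls$audit$rule == "topology" &
                    grepl("4602-4607", calls$audit$subject)))
  # the central region keeps its label support but no motif: non-canonical
  expect_true(any(calls$noncanonical_regions$start == 2402L))
})

test_that("hits straddling a region boundary are excluded and logged", {
  regions <- refine_regions(tibble::tibble(
    fragment_id = "a", start = 10L, end = 20L, labeled = TRUE,
    parent_id = NA_character_))
  hits <- tibble::tibble(seq_id = "s", pattern_id = "WALKER_A",
                         start = c(12L, 18L), end = c(17L, 23L),
                         matched = c("GAGAAG", "GAGAAG"))
  calls <- filter_motifs(hits, regions)
  expect_identical(calls$motifs$start, 12L)
  expect_true(any(calls$audit$rule == "containment" &
                    grepl("18-23", calls$audit$subject)))
  # empty hit list: every region is non-canonical
  calls0 <- filter_motifs(hits[0, ], regions)
  expect_identical(nrow(calls0$motifs), 0L)
  expect_identical(nrow(calls0$noncanonical_regions), 1L)
})

test_that("audit log covers every in-region hit exactly once", {
  seqs <- ryr1_standin()
  frag <- paper_fragments()
  labeled_spans <- frag[frag$labeled & !is.na(frag$start), ]
  hits <- scan_motifs(seqs)
  calls <- call_binding_regions(seqs, ryr1_fragments(),
                                topology = ryr1_topology(),
                                exclusions = ryr1_exclusions())
  in_labeled <- vapply(seq_len(nrow(hits)), function(i) {
    any(labeled_spans$start <= hits$start[i] &
          hits$end[i] <= labeled_spans$end)
  }, logical(1))
  tags <- paste0(hits$pattern_id, " ", hits$start, "-", hits$end)[in_labeled]
  surviving <- paste0(calls$motifs$pattern_id, " ", calls$motifs$start, "-",
                      calls$motifs$end)
  logged <- calls$audit$subject[calls$audit$rule %in%
                                  c("containment", "exclusion", "topology")]
  expect_identical(sum(tags %in% surviving) + sum(tags %in% logged),
                   length(tags))
})

test_that("extra unlabeled fragments or exclusions never add motifs", {
  # demotion off: with R3 active, a new unlabeled product can demote its
  # parent and thereby widen the root's region, so the monotonicity
  # guarantee is stated for the subtraction/narrowing rules alone
  seqs <- ryr1_standin()
  key <- function(calls) paste0(calls$motifs$pattern_id, ":",
                                calls$motifs$start)
  base_nd <- call_binding_regions(seqs, ryr1_fragments(),
                                  topology = ryr1_topology(),
                                  exclusions = ryr1_exclusions(),
                                  demote_on_unlabeled_products = FALSE)
  # an unlabeled product of fragment 8 removes part of the N-terminal region
  plus_unlab <- dplyr::bind_rows(
    ryr1_fragments(),
    tibble::tibble(fragment_id = "U", apparent_kda = NA_real_,
                   nterm_read = NA_character_, labeled = FALSE,
                   parent_id = "8", known_start = 427L, known_end = 1100L))
  narrowed <- call_binding_regions(seqs, plus_unlab,
                                   topology = ryr1_topology(),
                                   exclusions = ryr1_exclusions(),
                                   demote_on_unlabeled_products = FALSE)
  expect_true(all(key(narrowed) %in% key(base_nd)))
  expect_lt(length(key(narrowed)), length(key(base_nd)))
  # an extra exclusion span likewise only removes
  base <- call_binding_regions(seqs, ryr1_fragments(),
                               topology = ryr1_topology(),
                               exclusions = ryr1_exclusions())
  plus_excl <- dplyr::bind_rows(
    ryr1_exclusions(),
    tibble::tibble(start = 1195L, end = 1200L, reason = "test"))
  fewer <- call_binding_regions(seqs, ryr1_fragments(),
                                topology = ryr1_topology(),
                                exclusions = plus_excl)
  expect_true(all(key(fewer) %in% key(base)))
  expect_identical(length(key(fewer)), length(key(base)) - 1L)
})
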