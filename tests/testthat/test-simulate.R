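test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 4, length = 500,
                    motifs = tibble::tibble(pattern_id = "WALKER_A",
                                            position = 200L),
                    sites = 220L)
  a <- simulate_protein(cfg)
  b <- simulate_protein(cfg)
  expect_identical(a$sequence$residues, b$sequence$residues)
  fa <- simulate_observed_fragments(a$sequence, a$truth, cfg)
  fb <- simulate_observed_fragments(b$sequence, b$truth, cfg)
  expect_identical(fa, fb)
  ca <- simulate_curve(cfg)
  cb <- simulate_curve(cfg)
  expect_identical(ca$curve, cb$curve)
})

test_that("planted motifs are recovered by the scanner at their positions", {
  set.seed(1)
  for (i in 1:20) {
    pos <- sample(50:900, 3)
    cfg <- sim_config(seed = i, length = 1000,
                      motifs = tibble::tibble(
                        pattern_id = c("WALKER_A", "GROES", "WALKER_B_PARTIAL"),
                        position = as.integer(pos)))
    sim <- simulate_protein(cfg)
    hits <- scan_motifs(sim$sequence)
    for (k in 1:3) {
      expect_true(any(hits$pattern_id == cfg$motifs$pattern_id[k] &
                        hits$start == cfg$motifs$position[k]),
                  info = paste("seed", i, "plant", k))
    }
  }
})

test_that("degenerate composition yields the degenerate sequence", {
  cfg <- sim_config(seed = 2, length = 30,
                    composition = c(A = 1))
  sim <- simulate_protein(cfg)
  expect_identical(sim$sequence$residues, strrep("A", 30))
})

test_that("colliding plants raise an error", {
  cfg <- sim_config(seed = 3, length = 100,
                    motifs = tibble::tibble(
                      pattern_id = c("WALKER_A", "GROES"),
                      position = c(50L, 50L)))
  expect_error(simulate_protein(cfg), "collision")
})

test_that("labels follow site containment at zero false-negative rate", {
  cfg <- sim_config(seed = 12, length = 1200, sites = 600L,
                    n_fragments = 30, mass_sigma = 0, miscall_rate = 0)
  sim <- simulate_protein(cfg)
  frags <- simulate_observed_fragments(sim$sequence, sim$truth, cfg)
  expect_identical(frags$labeled,
                   frags$true_start <= 600L & frags$true_end >= 600L)
  # span boundaries are cleavage sites or termini
  sites <- cleavage_sites(sim$sequence$residues)
  expect_true(all(frags$true_start %in% c(1L, sites + 1L)))
  expect_true(all(frags$true_end %in% c(sites, sim$sequence$length)))
  # emitted parents contain their children
  has_parent <- !is.na(frags$parent_id)
  for (i in which(has_parent)) {
    p <- frags[frags$fragment_id == frags$parent_id[i], ]
    expect_lte(p$true_start, frags$true_start[i])
    expect_gte(p$true_end, frags$true_end[i])
  }
})

test_that("noiseless observations round-trip through the assigner", {
  cfg <- sim_config(seed = 21, length = 1500, sites = 700L,
                    n_fragments = 12, mass_sigma = 0, miscall_rate = 0)
  sim <- simulate_protein(cfg)
  frags <- simulate_observed_fragments(sim$sequence, sim$truth, cfg)
  asg <- assign_fragments(sim$sequence, frags)
  ok <- asg$status == "assigned"
  # every uniquely anchored fragment lands exactly on its true span, rank 1
  for (i in which(ok)) {
    expect_identical(asg$start[i], frags$true_start[i])
    expect_identical(asg$end[i], frags$true_end[i])
    expect_identical(asg$candidate_rank[i], 1L)
  }
  expect_gte(sum(ok), 1L)
})

test_that("zero-noise curves lie exactly on the model", {
  cfg <- sim_config(seed = 8, ic50_mM = 2, curve_sigma = 0, replicates = 1)
  sc <- simulate_curve(cfg)
  expect_equal(sc$curve$y, 1 / (1 + sc$curve$atp_mM / 2), tolerance = 1e-12)
  # midpoint: response at the true IC50 is one half
  cfg2 <- sim_config(seed = 8, ic50_mM = 2, curve_sigma = 0, replicates = 1,
                     concentrations = c(0.1, 1, 2, 10, 30))
  sc2 <- simulate_curve(cfg2)
  expect_equal(sc2$curve$y[sc2$curve$atp_mM == 2], 0.5)
})
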