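test_that("specific binding subtracts the competed ratio", {
  expect_equal(specific_signal(list(F800 = 800, F700 = 400),
                               list(F800 = 200, F700 = 400)), 1.5)
  rec <- list(F800 = 120, F700 = 60)
  expect_equal(specific_signal(rec, rec), 0)
  expect_warning(
    v <- specific_signal(list(F800 = 100, F700 = 400),
                         list(F800 = 300, F700 = 400)),
    "negative")
  expect_equal(v, -0.5)
  expect_error(specific_signal(list(F800 = 1, F700 = 0), rec), "positive")
})

test_that("curve normalisation follows (F - F0)/Fmax", {
  rec <- tibble::tibble(atp_mM = c(0, 1, 10), F = c(100, 50, 10))
  cc <- normalize_curve(rec, f0 = 0, fmax = 100)
  expect_equal(cc$y, c(1, 0.5, 0.1))
  # defaults: f0 = min signal, fmax = mean of no-competitor lanes
  cc2 <- normalize_curve(rec)
  expect_equal(cc2$y, c(0.9, 0.4, 0))
  expect_error(normalize_curve(rec, f0 = 0, fmax = 0), "fmax")
  expect_error(normalize_curve(rec[rec$atp_mM > 0, ]), "atp_mM == 0")
})

test_that("noiseless one-site curves are recovered exactly", {
  conc <- 10^seq(-2, 1.2, length.out = 8)
  cc <- tibble::tibble(atp_mM = conc, y = 1 / (1 + conc / 2))
  fit <- fit_ic50(cc)
  expect_equal(fit$ic50_mM, 2, tolerance = 1e-6)
  # model midpoint: y at the fitted IC50 is exactly 0.5
  expect_equal(1 / (1 + fit$ic50_mM / fit$ic50_mM), 0.5)
  # free Hill slope recovers both parameters on noiseless data
  cc2 <- tibble::tibble(atp_mM = conc, y = 1 / (1 + (conc / 0.8)^1.6))
  fit2 <- fit_ic50(cc2, hill = "free")
  expect_equal(fit2$ic50_mM, 0.8, tolerance = 1e-5)
  expect_equal(fit2$hill, 1.6, tolerance = 1e-5)
})

test_that("fitted IC50 is invariant to overall signal scale", {
  rec <- tibble::tibble(atp_mM = c(0, 10^seq(-2, 1.2, length.out = 8)))
  rec$F <- 400 / (1 + rec$atp_mM / 1.5) + 25
  for (k in c(1, 7.3, 1000)) {
    scaled <- dplyr::mutate(rec, F = F * k)
    cc <- normalize_curve(scaled, f0 = 25 * k, fmax = 400 * k)
    fit <- fit_ic50(cc)
    expect_equal(fit$ic50_mM, 1.5, tolerance = 1e-6)
  }
})

test_that("the fitted model is non-increasing in concentration", {
  cfg <- sim_config(seed = 99, ic50_mM = 1.2)
  fit <- fit_ic50(simulate_curve(cfg)$curve)
  grid <- 10^seq(-3, 2, length.out = 50)
  yy <- 1 / (1 + (grid / fit$ic50_mM)^fit$hill)
  expect_true(all(diff(yy) <= 0))
})

test_that("IC50 recovery has small median bias over 200 simulations", {
  est <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 5000 + i, ic50_mM = 1,
                      concentrations = 10^seq(-2, log10(50), length.out = 8),
                      curve_sigma = 0.05, replicates = 3)
    fit_ic50(simulate_curve(cfg)$curve)$ic50_mM
  }, numeric(1))
  expect_lte(abs(stats::median(est) - 1), 0.05)
})

test_that("degenerate inputs fail loudly", {
  flat <- tibble::tibble(atp_mM = 10^seq(-2, 1, length.out = 8), y = 0.5)
  expect_error(fit_ic50(flat), "flat")
  few <- tibble::tibble(atp_mM = c(0, 1, 2, 3), y = c(1, 0.5, 0.3, 0.2))
  expect_error(fit_ic50(few), "4 distinct non-zero")
})

test_that("tidy and glance expose the fit as tibbles", {
  cfg <- sim_config(seed = 77)
  fit <- fit_ic50(simulate_curve(cfg)$curve)
  td <- tidy(fit)
  expect_identical(td$term, "ic50_mM")
  gl <- glance(fit)
  expect_identical(gl$n_points, 24L)
  expect_true(gl$se >= 0)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
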