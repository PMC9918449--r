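mini_design <- function(seed = 1, archetype = "freely_drained",
                        rain = 300, n_realisations = 1, n_years = 2,
                        genotypes = list(genotype_preset("spring_susceptible"))) {
  factorial_design(
    sites = list(s1 = list(
      soil_archetype = archetype,
      weather_params = weather_gen_params(mean_annual_rain = rain,
                                          seed = 1L),
      latitude = 51,
      sowing_doys = c(ES = 90, LS = 120))),
    genotypes = genotypes,
    scenarios = list(baseline = list(deltas = climate_deltas())),
    n_realisations = n_realisations, n_years = n_years,
    start_year = 2000, master_seed = seed
  )
}

test_that("the factorial produces one paired row per cell-season", {
  d <- mini_design(n_realisations = 2, n_years = 3)
  res <- run_factorial(d, include_control = FALSE)
  # 1 site x 1 genotype x 2 sowing windows x 1 scenario x 2 realisations
  # x 3 years
  expect_equal(nrow(res), 12)
  expect_true(all(c("yield_default", "yield_wl") %in% names(res)))
  expect_true(all(res$yield_default >= 0))
})

test_that("an all-dry design has zero penalty everywhere", {
  d <- mini_design(rain = 250)
  res <- run_factorial(d, include_control = FALSE)
  expect_true(all(res$waterlogged_days == 0))
  expect_equal(res$yield_wl, res$yield_default)
})

test_that("the pipeline is deterministic under the master seed", {
  d <- mini_design(seed = 5)
  r1 <- run_factorial(d, include_control = FALSE)
  r2 <- run_factorial(d, include_control = FALSE)
  expect_identical(r1, r2)
})

test_that("penalty is non-negative across a fuzzed wet design", {
  d <- factorial_design(
    sites = list(wet = list(
      soil_archetype = "duplex_waterlogging_prone",
      weather_params = wet_winter_params(seed = 1),
      latitude = 51,
      sowing_doys = c(ES = 274, LS = 305))),
    genotypes = list(genotype_preset("winter_susceptible"),
                     genotype_preset("winter_tolerant")),
    scenarios = list(baseline = list(deltas = climate_deltas())),
    n_realisations = 2, n_years = 3, start_year = 2000, master_seed = 7
  )
  res <- run_factorial(d, include_control = FALSE)
  pen <- yield_penalty_pct(res$yield_default, res$yield_wl)
  # waterlogging physics cannot meaningfully raise yield; a delayed crop can
  # drift its growth window into brighter days, so allow a sub-0.05-point
  # second-order gain but nothing more
  expect_gte(min(pen), -0.05)
  expect_gte(stats::median(pen), 0)
  expect_gt(max(res$waterlogged_days), 0)  # the design did waterlog
})

test_that("frequency shift ANOVA and LSD letters match hand-worked cases", {
  # two periods, means 10 vs 20, unit within-period spread:
  # between-SS = 150 on 1 df, MSE = 1 on 4 df -> F = 150
  freqs <- data.frame(
    period = rep(c("base", "2080"), each = 3),
    realisation = rep(1:3, 2),
    pattern = "P0",
    pct = c(9, 10, 11, 19, 20, 21)
  )
  out <- frequency_shift_test(freqs)
  expect_equal(out$F[1], 150, tolerance = 1e-8)
  expect_lt(out$p_value[1], 0.05)
  expect_false(out$skipped[1])
  expect_equal(sort(unique(out$letter)), c("a", "b"))
  expect_equal(out$letter[out$period == "2080"], c("a", "a")[1])

  # identical frequencies: zero variance, test skipped
  same <- freqs; same$pct <- 10
  out2 <- frequency_shift_test(same)
  expect_true(all(out2$skipped))
  expect_true(all(is.na(out2$letter)))

  # equal means with noise: everyone shares a letter
  withr::with_seed(3, {
    noisy <- data.frame(
      period = rep(c("a", "b", "c"), each = 4),
      realisation = rep(1:4, 3), pattern = "P0",
      pct = 15 + rnorm(12, 0, 2))
  })
  out3 <- frequency_shift_test(noisy)
  expect_equal(length(unique(out3$letter)), 1)
  expect_gt(out3$p_value[1], 0.05)
})

test_that("per-realisation frequencies feed the shift test", {
  res <- data.frame(
    scenario = rep(c("baseline", "2080"), each = 4),
    realisation = rep(c(1, 1, 2, 2), 2),
    pattern = c("A", "A", "A", "B", "B", "B", "A", "B")
  )
  rf <- realisation_frequencies(res)
  expect_equal(nrow(rf), 8)  # 2 periods x 2 realisations x 2 patterns
  expect_true(all(tapply(rf$pct, interaction(rf$period, rf$realisation),
                         sum) == 100))
})

test_that("tolerance benefit is zero for an identical pair and flags empty selections", {
  res <- data.frame(
    site = "s1", genotype = rep(c("tol", "sus"), each = 6),
    sowing_window = "ES", scenario = "baseline",
    realisation = rep(1:2, 3), sowing_year = rep(2000:2002, each = 2),
    growing_season_rain = rep(c(300, 400, 500, 350, 450, 550), 2),
    yield_wl = rep(c(4000, 4100, 3900, 4050, 4200, 3800), 2)
  )
  tb <- tolerance_benefit(res, "tol", "sus", rainfall_percentile = 50)
  expect_true(all(tb$mean_benefit_kg_ha == 0))
  expect_warning(tolerance_benefit(res, "tol", "sus",
                                   rainfall_percentile = 100),
                 "empty")
  expect_error(tolerance_benefit(res, "tol", "missing"), "pair")
})
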