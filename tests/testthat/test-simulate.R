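test_that("CO2 response is normalised at 350 ppm and saturating", {
  expect_equal(f_co2(350), 1)
  expect_equal(f_co2(700), 1.2)
  expect_gt(f_co2(550), 1)
  expect_lt(f_co2(1000) - f_co2(900), f_co2(450) - f_co2(350))
})

test_that("daily growth is the product of its drivers", {
  expect_equal(daily_growth(20, 0.5, 1.2, 350, 1), 12)
  expect_equal(daily_growth(20, 0.5, 1.2, 350, 0), 0)
  expect_equal(daily_growth(0, 0.5, 1.2, 350, 1), 0)
  expect_equal(daily_growth(20, 0.5, 1.2, 700, 1), 12 * 1.2)
})

test_that("without waterlogging, tolerance parameters do not affect yield", {
  w <- constant_weather(2, rain = 1)   # light daily rain, freely draining
  sp <- generate_soil("freely_drained", seed = 3)
  m <- management(90)
  r_sus <- simulate_season(w, sp, genotype_preset("spring_susceptible"), m)
  r_tol <- simulate_season(w, sp, genotype_preset("spring_tolerant"), m)
  expect_equal(r_sus$waterlogged_days, 0)
  expect_equal(r_sus$yield, r_tol$yield)
  expect_gt(r_sus$yield, 1000)  # a real crop grew
  expect_true(r_sus$complete)
})

test_that("default mode equals waterlogging mode on a stress-free season", {
  w <- constant_weather(2, rain = 0.5)
  sp <- generate_soil("freely_drained", seed = 6)
  g <- genotype_preset("spring_susceptible")
  m <- management(100)
  r_wl <- simulate_season(w, sp, g, m, mode = "waterlogging")
  r_def <- simulate_season(w, sp, g, m, mode = "default")
  expect_equal(r_wl$yield, r_def$yield)
  expect_equal(r_wl$daily, r_def$daily)
  expect_equal(yield_penalty_pct(r_def$yield, r_wl$yield), 0)
})

test_that("waterlogging cuts yield, delays flowering, shortens grain fill", {
  w <- generate_weather(wet_winter_params(seed = 31), 3, 2000)
  sp <- generate_soil("duplex_waterlogging_prone", seed = 8)
  m <- management(288)
  sus <- simulate_season(w, sp, genotype_preset("winter_susceptible"), m)
  tol <- simulate_season(w, sp, genotype_preset("winter_tolerant"), m)
  unstressed <- simulate_season(w, sp, genotype_preset("winter_susceptible"),
                                m, mode = "default")
  expect_gt(sus$waterlogged_days, 0)
  expect_lt(sus$yield, tol$yield)
  expect_lt(sus$yield, unstressed$yield)
  # pre-flowering stress never advances flowering
  expect_gte(sus$flowering_das, unstressed$flowering_das)
  # post-flowering stress never lengthens grain fill
  expect_lte(sus$maturity_das - sus$flowering_das,
             unstressed$maturity_das - unstressed$flowering_das)
  # daily invariants
  expect_true(all(diff(sus$daily$stage) >= 0))
  expect_true(all(sus$daily$rtfr >= 0 & sus$daily$rtfr <= 1))
  expect_true(all(sus$daily$oxdef_photo >= 0 & sus$daily$oxdef_photo <= 1))
  expect_equal(sus$waterlogged_days, sum(sus$daily$oxdef_photo < 1))
})

test_that("yield is non-decreasing in the tolerance floor", {
  w <- generate_weather(wet_winter_params(seed = 31), 3, 2000)
  sp <- generate_soil("duplex_waterlogging_prone", seed = 8)
  m <- management(288)
  yields <- vapply(c(0, 0.3, 0.6, 1), function(fl) {
    g <- genotype("g", "winter", vern_sens = 4, photop_sens = 3,
                  tt_end_of_juvenile = 750, y_oxdef_lim_photo_floor = fl)
    simulate_season(w, sp, g, m)$yield
  }, numeric(1))
  expect_true(all(diff(yields) >= 0))
  expect_gt(yields[4], yields[1])  # tolerance matters on this season
})

test_that("a season that cannot reach maturity is flagged, not an error", {
  w <- constant_weather(1, rain = 0.5, maxt = 4, mint = -4)  # too cold
  sp <- generate_soil("freely_drained", seed = 3)
  r <- simulate_season(w, sp, genotype_preset("spring_susceptible"),
                       management(300))
  expect_false(r$complete)
  expect_equal(r$yield, 0)
})

test_that("sowing dates outside the series are rejected", {
  w <- constant_weather(1)
  sp <- generate_soil("freely_drained", seed = 3)
  expect_error(
    simulate_season(w, sp, genotype_preset("spring_susceptible"),
                    management(90), sowing_year = 1950),
    "not found")
})
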