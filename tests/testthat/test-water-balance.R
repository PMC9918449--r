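test_that("a drained profile at field capacity is inert without rain or ET", {
  sp <- toy_soil(k_sub = 100)
  w0 <- with(sp$layers, dul * thickness)
  out <- water_balance_step(sp, w0, rain = 0, potential_et = 0)
  expect_equal(out$layer_water, w0)
  expect_equal(out$drainage, 0)
  expect_equal(out$runoff, 0)
  expect_equal(out$actual_et, 0)
  expect_false(any(out$saturated))
})

test_that("heavy rain on an impermeable subsoil matches hand-worked arithmetic", {
  # two layers: caps (LL, DUL, SAT) = (20, 50, 70) and (36, 84, 114) mm;
  # 100 mm of rain: 50 mm passes L1 (k limit) but only 30 fits in L2 (to
  # SAT); L1 then holds 120 > 70 so 50 mm backs out as runoff; no drainage
  # through the k = 0 subsoil
  sp <- toy_soil(k_sub = 0)
  w0 <- with(sp$layers, dul * thickness)
  out <- water_balance_step(sp, w0, rain = 100, potential_et = 0)
  expect_equal(out$layer_water, c(70, 114))
  expect_equal(out$runoff, 50)
  expect_equal(out$drainage, 0)
  expect_true(all(out$saturated))
  expect_equal(100, out$storage_change + out$drainage + out$runoff +
                 out$actual_et, tolerance = 1e-9)
})

test_that("layers below the water table are permanently saturated", {
  sp <- toy_soil(k_sub = 10, water_table = 300)
  w0 <- with(sp$layers, ll * thickness)
  for (rain in c(0, 5)) {
    out <- water_balance_step(sp, w0, rain = rain, potential_et = 2)
    expect_true(out$saturated[2])  # bottom 200-500 mm straddles the table
    w0 <- out$layer_water
  }
})

test_that("daily mass balance closes to 1e-6 mm on fuzzed inputs", {
  archetypes <- c("freely_drained", "duplex_waterlogging_prone",
                  "shallow_water_table")
  withr::with_seed(314, {
    for (rep in seq_len(10)) {
      sp <- generate_soil(sample(archetypes, 1), seed = sample.int(1e6, 1))
      caps <- with(sp$layers, sat * thickness)
      w <- runif(nrow(sp$layers)) * caps
      for (day in seq_len(100)) {
        rain <- if (runif(1) < 0.4) runif(1, 0, 80) else 0
        pet <- runif(1, 0, 8)
        out <- water_balance_step(sp, w, rain, pet,
                                  et_depth = runif(1, 100, 1500))
        expect_equal(rain,
                     out$storage_change + out$drainage + out$runoff +
                       out$actual_et,
                     tolerance = 1e-6)
        expect_true(all(out$layer_water >= -1e-9))
        expect_true(all(out$layer_water <= caps + 1e-9))
        w <- out$layer_water
      }
    }
  })
})

test_that("negative rain or ET is rejected", {
  sp <- toy_soil()
  w0 <- with(sp$layers, dul * thickness)
  expect_error(water_balance_step(sp, w0, -1, 0), ">= 0")
  expect_error(water_balance_step(sp, w0, 0, -1), ">= 0")
})

test_that("fraction of roots waterlogged prorates partial layers", {
  sp <- soil_profile(data.frame(thickness = c(300, 300),
                                ll = 0.1, dul = 0.25, sat = 0.35,
                                k_sat = 10))
  expect_equal(fraction_roots_waterlogged(600, c(FALSE, FALSE), sp), 0)
  expect_equal(fraction_roots_waterlogged(600, c(TRUE, TRUE), sp), 1)
  # bottom 300 mm of a 600 mm root zone saturated
  expect_equal(fraction_roots_waterlogged(600, c(FALSE, TRUE), sp), 0.5)
  # roots only partway into the saturated layer
  expect_equal(fraction_roots_waterlogged(450, c(FALSE, TRUE), sp),
               150 / 450)
  # pre-emergence
  expect_equal(fraction_roots_waterlogged(0, c(TRUE, TRUE), sp), 0)
  expect_error(fraction_roots_waterlogged(-5, c(TRUE, TRUE), sp), ">= 0")
})

test_that("potential ET rises with radiation and temperature", {
  expect_gt(potential_et(25, 30, 15), potential_et(10, 30, 15))
  expect_gt(potential_et(15, 30, 20), potential_et(15, 10, 2))
  expect_gte(potential_et(1, -5, -15), 0)
})
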