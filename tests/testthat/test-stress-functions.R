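test_that("photosynthesis stress index matches its printed anchors", {
  expect_equal(oxdef_photo_factor(0), 1)
  expect_equal(oxdef_photo_factor(0.5), 1)    # below threshold: no stress
  expect_equal(oxdef_photo_factor(0.8), 1)    # threshold itself
  expect_equal(oxdef_photo_factor(0.9), 0.5)  # midpoint of the ramp
  expect_equal(oxdef_photo_factor(1), 0)      # fully saturated profile
})

test_that("phenology stress index matches its printed anchors", {
  expect_equal(oxdef_pheno_factor(0.7), 1)
  expect_equal(oxdef_pheno_factor(0.8), 1)
  expect_equal(oxdef_pheno_factor(0.9), 0.9)
  expect_equal(oxdef_pheno_factor(1), 0.8)
})

test_that("stress indices are non-increasing, continuous and 1 below 0.8", {
  rtfr <- seq(0, 1, by = 0.001)
  for (f in list(oxdef_photo_factor, oxdef_pheno_factor)) {
    y <- f(rtfr)
    expect_true(all(diff(y) <= 1e-12))
    expect_true(all(y[rtfr < 0.8] == 1))
    # continuity: no jump larger than the local slope allows
    expect_lt(max(abs(diff(y))), 0.01)
  }
})

test_that("stress indices reject out-of-range drivers", {
  expect_error(oxdef_photo_factor(-0.1), "rtfr")
  expect_error(oxdef_pheno_factor(1.1), "rtfr")
})

test_that("stage modifier reproduces the anchor table and interpolates", {
  expect_equal(stage_modifier_pheno(4), 0.65)
  expect_equal(stage_modifier_pheno(5.5), 0.95)
  expect_equal(stage_modifier_pheno(6), 1.0)
  expect_equal(stage_modifier_pheno(10), 1.5)
  expect_equal(stage_modifier_pheno(8), 1.25)   # midpoint of the 6-10 ramp
  expect_equal(stage_modifier_pheno(2), 0.65)   # flat extension below 4
  expect_equal(stage_modifier_pheno(10.5), 1.5) # flat above 10
  expect_error(stage_modifier_pheno(0.5), "stage")
  # below 1 strictly before flowering, 1 and above from flowering on
  st <- seq(1, 11, by = 0.01)
  y <- stage_modifier_pheno(st)
  expect_true(all(y[st < 6] < 1))
  expect_true(all(y[st >= 6] >= 1))
})

test_that("three-stage response follows lag, full-stress and adapted floor", {
  sus <- genotype("s", "spring", y_oxdef_lim_photo_floor = 0.6,
                  lag_days = 3, adapt_days = 10)
  tol <- genotype("t", "spring", y_oxdef_lim_photo_floor = 1,
                  lag_days = 3, adapt_days = 10)
  # stage one: growth unaffected on the first saturated days
  expect_equal(three_stage_response(0, 0, sus), 1)
  expect_equal(three_stage_response(3, 0, sus), 1)
  # stage two: raw stress applies in full
  expect_equal(three_stage_response(4, 0, sus), 0)
  expect_equal(three_stage_response(13, 0.25, sus), 0.25)
  # stage three: adapted floor
  expect_equal(three_stage_response(14, 0, sus), 0.6)
  expect_equal(three_stage_response(100, 0.7, sus), 0.7)  # floor is a floor
  # fully tolerant genotype recovers pre-waterlogging rates
  expect_equal(three_stage_response(14, 0, tol), 1)
  expect_equal(three_stage_response(1000, 0, tol), 1)
})

test_that("model constants validate overrides and reject unknown keys", {
  expect_error(wl_constants(nonsense = 1), "unknown")
  expect_error(wl_constants(rtfr_threshold = 1.5))
  cc <- wl_constants(lag_days = 5)
  expect_equal(cc$lag_days, 5)
  # threshold override moves the stress onset
  c9 <- wl_constants(rtfr_threshold = 0.9)
  expect_equal(oxdef_photo_factor(0.85, c9), 1)
  expect_equal(oxdef_photo_factor(0.95, c9), 0.5)
})
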