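test_that("degenerate occurrence chain produces an all-dry series", {
  p <- weather_gen_params(p_wet_wet = 0, p_dry_wet = 0, seed = 4)
  w <- generate_weather(p, 2, 2000)
  expect_true(all(w$records$rain == 0))
})

test_that("same parameters and seed give identical series", {
  p <- weather_gen_params(seed = 99)
  w1 <- generate_weather(p, 3, 1990)
  w2 <- generate_weather(p, 3, 1990)
  expect_identical(w1, w2)
  w3 <- generate_weather(weather_gen_params(seed = 100), 3, 1990)
  expect_false(identical(w1$records$rain, w3$records$rain))
})

test_that("long-run rainfall converges to the occurrence-amount expectation", {
  p <- weather_gen_params(mean_annual_rain = 700, seed = 21)
  w <- generate_weather(p, 200, 1800 + 100)  # 200 years
  realised <- sum(w$records$rain) / 200
  # oracle: E(annual) = 365.25 * P(wet) * shape * scale with the stationary
  # Markov wet probability; the generator derives scale to hit the target
  p_wet <- p$p_dry_wet / (1 + p$p_dry_wet - p$p_wet_wet)
  expect_equal(realised / 700, 1, tolerance = 0.05)
  # wet-day frequency converges to the stationary probability
  expect_equal(mean(w$records$rain > 0) / p_wet, 1, tolerance = 0.05)
})

test_that("weather validity invariants hold across seeds", {
  for (seed in c(1, 17, 202, 4040)) {
    w <- generate_weather(weather_gen_params(seed = seed), 2, 2000)
    r <- w$records
    expect_true(all(r$maxt >= r$mint))
    expect_true(all(r$rain >= 0))
    expect_true(all(r$radn > 0))
    # contiguous calendar including the 2000 leap day
    expect_equal(nrow(r), 366 + 365)
  }
})

test_that("wet days are cooler and dimmer than dry days in expectation", {
  w <- generate_weather(weather_gen_params(seed = 8), 30, 1900)
  r <- w$records
  wet <- r$rain > 0
  expect_lt(mean(r$maxt[wet]), mean(r$maxt[!wet]))
  expect_lt(mean(r$radn[wet]), mean(r$radn[!wet]))
})

test_that("invalid generator parameters are rejected", {
  expect_error(weather_gen_params(p_wet_wet = 1.2), "probabilit")
  expect_error(weather_gen_params(rain_gamma_shape = -1), "shape")
  expect_error(weather_gen_params(ar1_temp = 1), "ar1")
})

test_that("identity deltas return the series unchanged", {
  w <- generate_weather(weather_gen_params(seed = 3), 2, 2001)
  w2 <- apply_climate_deltas(w, climate_deltas(), "baseline")
  expect_equal(w2$records, w$records)
})

test_that("deltas shift temperatures and scale rain/radn by calendar month", {
  w <- generate_weather(weather_gen_params(seed = 3), 1, 2001)
  d <- climate_deltas(monthly_temp_offset = rep(2, 12),
                      monthly_rain_factor = rep(0, 12))
  w2 <- apply_climate_deltas(w, d, "2080")
  expect_equal(w2$records$maxt, w$records$maxt + 2)
  expect_equal(w2$records$mint, w$records$mint + 2)
  expect_true(all(w2$records$rain == 0))
  expect_equal(w2$records$radn, w$records$radn)
  expect_equal(w2$scenario_tag, "2080")
  # month-specific factor applies only to that month
  dj <- climate_deltas(monthly_rain_factor = c(2, rep(1, 11)))
  w3 <- apply_climate_deltas(w, dj, "jan2x")
  jan <- w$records$doy <= 31
  expect_equal(w3$records$rain[jan], 2 * w$records$rain[jan])
  expect_equal(w3$records$rain[!jan], w$records$rain[!jan])
})

test_that("delta composition is additive in offsets", {
  w <- generate_weather(weather_gen_params(seed = 5), 1, 2002)
  d1 <- climate_deltas(monthly_temp_offset = rep(1, 12))
  d2 <- climate_deltas(monthly_temp_offset = rep(2, 12))
  once_twice <- apply_climate_deltas(apply_climate_deltas(w, d1, "a"),
                                     d1, "b")
  at_once <- apply_climate_deltas(w, d2, "b")
  expect_equal(once_twice$records, at_once$records)
})

test_that("negative rain factors are rejected", {
  expect_error(climate_deltas(monthly_rain_factor = rep(-1, 12)),
               "rain factors")
})
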