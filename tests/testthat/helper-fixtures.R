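# Shared fixtures: small deterministic inputs built in code.

# two-layer hand-checkable soil
toy_soil <- function(k_sub = 0, water_table = NA_real_) {
  soil_profile(
    data.frame(thickness = c(200, 300),
               ll = c(0.10, 0.12), dul = c(0.25, 0.28),
               sat = c(0.35, 0.38), k_sat = c(50, k_sub)),
    water_table_depth = water_table
  )
}

# constant benign weather: dry, mild, bright
constant_weather <- function(n_years = 2, start_year = 2000, rain = 0,
                             maxt = 20, mint = 10, radn = 18,
                             latitude = 51) {
  cal <- do.call(rbind, lapply(seq(start_year, length.out = n_years),
                               function(y) {
    n <- if (y %% 4 == 0 && (y %% 100 != 0 || y %% 400 == 0)) 366 else 365
    data.frame(year = y, doy = seq_len(n))
  }))
  cal$radn <- radn; cal$maxt <- maxt; cal$mint <- mint; cal$rain <- rain
  yrs <- unique(cal$year)
  weather_series("toy", latitude, cal,
                 stats::setNames(co2_for_year(yrs), yrs))
}

# brute-force minimum-WSS partition of points into k non-empty clusters
brute_force_kmeans <- function(x, k) {
  n <- nrow(x)
  best <- NULL
  assign_next <- function(assigned, next_i) {
    if (next_i > n) {
      if (length(unique(assigned)) != k) return()
      wss <- sum(vapply(unique(assigned), function(j) {
        xi <- x[assigned == j, , drop = FALSE]
        sum(sweep(xi, 2, colMeans(xi))^2)
      }, numeric(1)))
      if (is.null(best) || wss < best$wss - 1e-12) {
        best <<- list(wss = wss, assigned = assigned)
      }
      return()
    }
    # canonical form: cluster labels appear in order of first use
    top <- if (next_i == 1) 0 else max(assigned)
    for (j in seq_len(min(top + 1, k))) {
      assign_next(c(assigned, j), next_i + 1)
    }
  }
  assign_next(integer(0), 1)
  best
}

# planted stress-vector archetypes with noise
planted_vectors <- function(n, seed, sd = 0.05) {
  arch <- rbind(
    none = rep(1, 6),
    early_severe = c(0.2, 0.35, 0.9, 1, 1, 1),
    late_moderate = c(1, 1, 1, 0.9, 0.75, 0.8),
    late_severe = c(1, 1, 0.95, 0.5, 0.25, 0.35)
  )
  withr::with_seed(seed, {
    ix <- sample(seq_len(4), n, replace = TRUE)
    x <- arch[ix, ]
    x <- x + stats::rnorm(length(x), 0, sd)
    x <- pmax(pmin(x, 1), 0)
    list(x = x, truth = rownames(arch)[ix])
  })
}

# weather params used in waterlogging scenarios: wet winter-peak climate
wet_winter_params <- function(seed, mean_annual_rain = 850) {
  weather_gen_params(mean_annual_rain = mean_annual_rain,
                     p_wet_wet = 0.65, p_dry_wet = 0.28,
                     rain_peak_doy = 15, rain_seasonality = 0.5,
                     temp_mean = 10, seed = seed)
}
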