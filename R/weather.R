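#' Stochastic weather generator parameters
#'
#' Parameters of the seeded daily weather generator: a first-order two-state
#' Markov chain for rainfall occurrence, gamma-distributed wet-day amounts
#' with a sinusoidal seasonal modulation of the mean amount, sinusoidal annual
#' cycles for temperature and radiation with AR(1) residuals, and fixed
#' wet-day depressions of temperature and radiation (rainy days are cooler
#' and receive less radiation).
#'
#' The gamma scale is derived internally from `mean_annual_rain`, the
#' stationary wet-day probability of the Markov chain and `rain_gamma_shape`,
#' so that the expected annual rainfall equals `mean_annual_rain`:
#' `E(annual rain) = 365.25 * P(wet) * shape * scale` with
#' `P(wet) = p_dry_wet / (1 + p_dry_wet - p_wet_wet)`.
#'
#' @param mean_annual_rain Mean annual rainfall, mm.
#' @param rain_peak_doy Day of year at which mean wet-day amounts peak.
#' @param rain_seasonality Relative amplitude (0 to <1) of the seasonal
#'   modulation of wet-day amounts.
#' @param p_wet_wet Probability a wet day follows a wet day.
#' @param p_dry_wet Probability a wet day follows a dry day.
#' @param rain_gamma_shape Gamma shape of wet-day amounts.
#' @param temp_mean Annual mean of daily mean temperature, deg C.
#' @param temp_amplitude Semi-amplitude of the annual temperature cycle, deg C.
#' @param temp_peak_doy Day of year of the warmest mean temperature.
#' @param diurnal_range Mean difference maxt - mint, deg C (kept >= 1).
#' @param radn_mean Annual mean daily solar radiation, MJ/m2/day.
#' @param radn_amplitude Semi-amplitude of the annual radiation cycle.
#' @param wet_day_temp_depression Reduction of mean temperature on wet days,
#'   deg C.
#' @param wet_day_radn_factor Multiplier on radiation for wet days (0 to 1).
#' @param ar1_temp,ar1_sd AR(1) coefficient and innovation standard deviation
#'   of the temperature residual.
#' @param seed Integer seed; the same parameters and seed give a
#'   byte-identical series.
#' @return A list with class `weather_gen_params`.
#' @export
weather_gen_params <- function(mean_annual_rain = 700,
                               rain_peak_doy = 15,
                               rain_seasonality = 0.5,
                               p_wet_wet = 0.6,
                               p_dry_wet = 0.25,
                               rain_gamma_shape = 0.8,
                               temp_mean = 10,
                               temp_amplitude = 7,
                               temp_peak_doy = 200,
                               diurnal_range = 9,
                               radn_mean = 13,
                               radn_amplitude = 8,
                               wet_day_temp_depression = 2,
                               wet_day_radn_factor = 0.6,
                               ar1_temp = 0.6,
                               ar1_sd = 2,
                               seed = 1L) {
  p <- list(
    mean_annual_rain = mean_annual_rain, rain_peak_doy = rain_peak_doy,
    rain_seasonality = rain_seasonality, p_wet_wet = p_wet_wet,
    p_dry_wet = p_dry_wet, rain_gamma_shape = rain_gamma_shape,
    temp_mean = temp_mean, temp_amplitude = temp_amplitude,
    temp_peak_doy = temp_peak_doy, diurnal_range = diurnal_range,
    radn_mean = radn_mean, radn_amplitude = radn_amplitude,
    wet_day_temp_depression = wet_day_temp_depression,
    wet_day_radn_factor = wet_day_radn_factor,
    ar1_temp = ar1_temp, ar1_sd = ar1_sd, seed = as.integer(seed)
  )
  validate_weather_gen_params(p)
  structure(p, class = "weather_gen_params")
}

validate_weather_gen_params <- function(p) {
  probs <- c(p$p_wet_wet, p$p_dry_wet)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("occurrence probabilities must lie in [0, 1]")
  }
  if (!is.finite(p$rain_gamma_shape) || p$rain_gamma_shape <= 0) {
    stop("gamma shape must be > 0")
  }
  if (p$mean_annual_rain < 0) stop("mean annual rainfall must be >= 0")
  if (p$rain_seasonality < 0 || p$rain_seasonality >= 1) {
    stop("rain_seasonality must lie in [0, 1)")
  }
  if (p$wet_day_radn_factor <= 0 || p$wet_day_radn_factor > 1) {
    stop("wet_day_radn_factor must lie in (0, 1]")
  }
  if (abs(p$ar1_temp) >= 1) stop("ar1_temp must lie in (-1, 1)")
  invisible(p)
}

#' Daily weather series
#'
#' Container for a contiguous daily weather record at one site: year, day of
#' year, solar radiation (MJ/m2/day), maximum and minimum temperature (deg C)
#' and rainfall (mm), plus a per-year atmospheric CO2 map and a scenario tag
#' (e.g. `"baseline"`, `"2040"`, `"2080"`).
#'
#' @param site_id Site identifier.
#' @param latitude Latitude in degrees; negative for the southern hemisphere
#'   (sets the photoperiod calculation).
#' @param records data.frame with columns `year`, `doy`, `radn`, `maxt`,
#'   `mint`, `rain`, contiguous in (year, doy).
#' @param co2_ppm_by_year Named numeric vector mapping year to ppm; must
#'   cover every year in `records`.
#' @param scenario_tag Scenario label.
#' @return A list with class `weather_series`.
#' @export
weather_series <- function(site_id, latitude, records, co2_ppm_by_year,
                           scenario_tag = "baseline") {
  stopifnot(is.data.frame(records),
            all(c("year", "doy", "radn", "maxt", "mint", "rain") %in%
                  names(records)))
  validate_weather_records(records)
  years <- unique(records$year)
  if (!all(as.character(years) %in% names(co2_ppm_by_year))) {
    stop("co2_ppm_by_year must cover every simulated year")
  }
  structure(list(
    site_id = site_id, latitude = latitude, records = records,
    co2_ppm_by_year = co2_ppm_by_year, scenario_tag = scenario_tag
  ), class = "weather_series")
}

validate_weather_records <- function(records, where = "weather records") {
  bad <- which(records$maxt < records$mint)
  if (length(bad)) {
    stop(where, ": maxt < mint at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(records$rain < 0)) stop(where, ": negative rainfall")
  if (any(records$radn <= 0)) stop(where, ": non-positive radiation")
  if (any(!is.finite(as.matrix(records[c("radn", "maxt", "mint", "rain")])))) {
    stop(where, ": non-finite value in numeric fields")
  }
  expected <- expand_doy(unique(records$year))
  if (nrow(records) != nrow(expected) ||
      any(records$year != expected$year) || any(records$doy != expected$doy)) {
    stop(where, ": records are not contiguous in (year, doy)")
  }
  invisible(records)
}

days_in_year <- function(year) {
  ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0), 366L, 365L)
}

expand_doy <- function(years) {
  years <- sort(years)
  n <- days_in_year(years)
  data.frame(year = rep(years, n),
             doy = unlist(lapply(n, seq_len), use.names = FALSE))
}

#' @export
print.weather_series <- function(x, ...) {
  yrs <- range(x$records$year)
  cat("<weather_series> ", x$site_id, " (lat ", x$latitude, "), scenario ",
      x$scenario_tag, "\n  ", nrow(x$records), " days, ", yrs[1], "-", yrs[2],
      ", mean annual rain ",
      round(sum(x$records$rain) / length(unique(x$records$year))), " mm\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic daily weather series
#'
#' Simulates `n_years` of daily weather from [weather_gen_params()]:
#' first-order Markov wet/dry occurrence (producing realistic multi-day wet
#' spells), gamma wet-day rainfall with seasonal mean modulation, sinusoidal
#' temperature/radiation annual cycles with AR(1) temperature residuals, and
#' wet-day temperature/radiation depressions. Deterministic under a fixed
#' seed. Leap days (doy 366) are generated like any other day of the same
#' season.
#'
#' @param params A [weather_gen_params()] object.
#' @param n_years Number of years to simulate (>= 1).
#' @param start_year First calendar year.
#' @param site_id,latitude Site metadata (latitude sign selects hemisphere
#'   for downstream photoperiod).
#' @param co2_source Either the function [co2_for_year()] (default) or a
#'   named numeric table year -> ppm used to populate the CO2 map.
#' @return A [weather_series()].
#' @examples
#' w <- generate_weather(weather_gen_params(seed = 42), n_years = 2,
#'                       start_year = 1990)
#' head(w$records)
#' @export
generate_weather <- function(params, n_years, start_year = 1985,
                             site_id = "site", latitude = 51,
                             co2_source = co2_for_year) {
  stopifnot(inherits(params, "weather_gen_params"), n_years >= 1)
  validate_weather_gen_params(params)
  years <- seq.int(start_year, start_year + n_years - 1)
  cal <- expand_doy(years)
  n <- nrow(cal)
  p_wet_stat <- stationary_wet_prob(params)

  with_seed(params$seed, {
    # occurrence: first-order two-state Markov chain
    u <- stats::runif(n)
    wet <- logical(n)
    wet[1] <- u[1] < p_wet_stat
    for (i in 2:n) {
      p <- if (wet[i - 1]) params$p_wet_wet else params$p_dry_wet
      wet[i] <- u[i] < p
    }
    # amounts: gamma, scale derived from the annual rainfall target and
    # modulated seasonally (annual mean of the modulation is ~1)
    base_scale <- if (p_wet_stat > 0 && params$mean_annual_rain > 0) {
      params$mean_annual_rain / (365.25 * p_wet_stat * params$rain_gamma_shape)
    } else {
      1
    }
    season <- cos(2 * pi * (cal$doy - params$rain_peak_doy) / 365.25)
    scale_t <- base_scale * (1 + params$rain_seasonality * season)
    rain <- numeric(n)
    nw <- sum(wet)
    if (nw > 0) {
      rain[wet] <- stats::rgamma(nw, shape = params$rain_gamma_shape,
                                 scale = scale_t[wet])
    }
    rain <- round(rain, 2)

    # temperature: annual cycle + wet-day depression + AR(1) residual
    tcycle <- params$temp_mean + params$temp_amplitude *
      cos(2 * pi * (cal$doy - params$temp_peak_doy) / 365.25) *
      sign_hemisphere(latitude)
    eps <- stats::rnorm(n, 0, params$ar1_sd)
    resid <- stats::filter(eps, params$ar1_temp, method = "recursive")
    tmean <- tcycle - params$wet_day_temp_depression * wet + as.numeric(resid)
    range_day <- pmax(1, params$diurnal_range + stats::rnorm(n, 0, 1.5) -
                        2 * wet)
    maxt <- round(tmean + range_day / 2, 1)
    mint <- round(tmean - range_day / 2, 1)

    # radiation: annual cycle, wet-day multiplicative depression
    rcycle <- params$radn_mean + params$radn_amplitude *
      cos(2 * pi * (cal$doy - params$temp_peak_doy) / 365.25) *
      sign_hemisphere(latitude)
    radn <- rcycle * ifelse(wet, params$wet_day_radn_factor, 1) *
      exp(stats::rnorm(n, 0, 0.08))
    radn <- round(pmax(0.5, radn), 1)

    records <- data.frame(year = cal$year, doy = cal$doy, radn = radn,
                          maxt = maxt, mint = mint, rain = rain)
    co2 <- if (is.function(co2_source)) {
      stats::setNames(vapply(years, co2_source, numeric(1)),
                      as.character(years))
    } else {
      if (!all(as.character(years) %in% names(co2_source))) {
        stop("co2_source table does not cover all simulated years")
      }
      co2_source[as.character(years)]
    }
    weather_series(site_id, latitude, records, co2, "baseline")
  })
}

# Stationary wet-day probability of the two-state occurrence chain.
stationary_wet_prob <- function(params) {
  denom <- 1 + params$p_dry_wet - params$p_wet_wet
  if (denom <= 0) return(1)
  params$p_dry_wet / denom
}

# +1 for northern hemisphere (warmest mid-year when temp_peak_doy ~ 200);
# -1 flips the annual cycle for southern-hemisphere sites.
sign_hemisphere <- function(latitude) if (latitude < 0) -1 else 1

#' Monthly delta-change climate perturbation
#'
#' Monthly additive temperature offsets and multiplicative rainfall/radiation
#' factors used to construct future-climate variants of a baseline series
#' (stand-in for downscaled GCM trends). Identity deltas are offset 0 and
#' factors 1.
#'
#' @param monthly_temp_offset 12 temperature offsets, deg C.
#' @param monthly_rain_factor 12 rainfall multipliers, >= 0.
#' @param monthly_radn_factor 12 radiation multipliers, > 0.
#' @return A list with class `climate_deltas`.
#' @export
climate_deltas <- function(monthly_temp_offset = rep(0, 12),
                           monthly_rain_factor = rep(1, 12),
                           monthly_radn_factor = rep(1, 12)) {
  stopifnot(length(monthly_temp_offset) == 12,
            length(monthly_rain_factor) == 12,
            length(monthly_radn_factor) == 12)
  if (any(!is.finite(c(monthly_temp_offset, monthly_rain_factor,
                       monthly_radn_factor)))) {
    stop("climate deltas must be finite")
  }
  if (any(monthly_rain_factor < 0)) stop("rain factors must be >= 0")
  if (any(monthly_radn_factor <= 0)) stop("radiation factors must be > 0")
  structure(list(monthly_temp_offset = monthly_temp_offset,
                 monthly_rain_factor = monthly_rain_factor,
                 monthly_radn_factor = monthly_radn_factor),
            class = "climate_deltas")
}

#' Apply monthly climate deltas to a weather series
#'
#' Shifts maximum and minimum temperature by the calendar month's offset and
#' scales rainfall and radiation by the month's factors, preserving record
#' order and count. Identity deltas return an equal series.
#'
#' @param series A [weather_series()].
#' @param deltas A [climate_deltas()].
#' @param scenario_tag Tag for the perturbed series (e.g. `"2080"`).
#' @param co2_source Optional replacement CO2 map for the scenario: the
#'   function [co2_for_year()], a named table, or `NULL` to keep the
#'   baseline map.
#' @return A perturbed [weather_series()].
#' @export
apply_climate_deltas <- function(series, deltas, scenario_tag = "scenario",
                                 co2_source = NULL) {
  stopifnot(inherits(series, "weather_series"),
            inherits(deltas, "climate_deltas"))
  rec <- series$records
  month <- doy_to_month(rec$doy, rec$year)
  rec$maxt <- rec$maxt + deltas$monthly_temp_offset[month]
  rec$mint <- rec$mint + deltas$monthly_temp_offset[month]
  rec$rain <- rec$rain * deltas$monthly_rain_factor[month]
  rec$radn <- rec$radn * deltas$monthly_radn_factor[month]
  co2 <- series$co2_ppm_by_year
  if (is.function(co2_source)) {
    years <- unique(rec$year)
    co2 <- stats::setNames(vapply(years, co2_source, numeric(1)),
                           as.character(years))
  } else if (!is.null(co2_source)) {
    co2 <- co2_source
  }
  weather_series(series$site_id, series$latitude, rec, co2, scenario_tag)
}

doy_to_month <- function(doy, year) {
  as.integer(format(as.Date(doy - 1, origin = paste0(year, "-01-01")), "%m"))
}

#' SSP585 atmospheric CO2 trajectory
#'
#' Yearly atmospheric CO2 concentration (ppm) under the high-emission SSP585
#' pathway, from an empirical regression against an ensemble of CMIP6 global
#' circulation models, valid for calendar years 1900 to 2100.
#'
#' @param y Calendar year(s), 1900 to 2100.
#' @return CO2 concentration(s), ppm.
#' @examples
#' co2_for_year(c(1985, 2040, 2080))
#' @export
co2_for_year <- function(y) {
  if (!is.numeric(y) || anyNA(y) || any(y < 1900 | y > 2100)) {
    stop("year must lie in [1900, 2100]")
  }
  757.44 +
    (84.938 - 1.537 * y) / (2.2011 - 3.8289 * y^(-0.45242)) +
    2.4712e-4 * (y + 15)^2 +
    1.9299e-5 * (y - 1937) * 1e-5 * (y - 1937)^3 +
    5.1137e-7 * (y - 1910)^4
}
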