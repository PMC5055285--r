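#' Site configuration
#'
#' Describes one rocky-shore study site: location, the local-time offset used
#' to define calendar days, the elevation of the logger bed above the MLLW
#' tidal datum (mid-intertidal mussel beds sit around +1.5 m), the shore
#' slope entering the wave run-up proxy, and the number of biomimetic loggers
#' deployed.
#'
#' @param site_id Character label.
#' @param latitude,longitude Decimal degrees; latitude in \[-90, 90\].
#' @param utc_offset Hours to add to UTC for local standard time.
#' @param logger_elevation Metres above MLLW, > 0.
#' @param shore_slope Dimensionless rise/run, > 0.
#' @param n_loggers Number of loggers, >= 1.
#' @return A list of class `site_config`.
#' @export
site_config <- function(site_id = "site_1",
                        latitude = 44.83, longitude = -124.06,
                        utc_offset = -8,
                        logger_elevation = 1.5,
                        shore_slope = 0.2,
                        n_loggers = 3) {
  if (latitude < -90 || latitude > 90) stop("latitude must be in [-90, 90]")
  if (logger_elevation <= 0) stop("logger_elevation must be > 0")
  if (shore_slope <= 0) stop("shore_slope must be > 0")
  if (n_loggers < 1) stop("n_loggers must be >= 1")
  structure(list(site_id = site_id, latitude = latitude, longitude = longitude,
                 utc_offset = utc_offset, logger_elevation = logger_elevation,
                 shore_slope = shore_slope, n_loggers = n_loggers),
            class = "site_config")
}

#' Synthetic-forcing generator configuration
#'
#' Controls the seeded generator of environmental forcing and "true" logger
#' records. Air temperature is a mean plus seasonal and diurnal sinusoids
#' plus first-order autoregressive noise; shortwave irradiance is a
#' clear-sky geometric curve modulated by an autocorrelated cloud
#' transmission in \[0, 1\]; tide height is a sum of harmonic constituents
#' around a mean level; wind and wave height are positive (lognormal)
#' autocorrelated processes. Logger truth adds per-logger microsite offsets,
#' wave-splash resets toward sea-surface temperature and i.i.d. instrument
#' noise (default 2 degC, the accuracy with which biomimetic loggers track
#' live mussels).
#'
#' @param seed Integer RNG seed.
#' @param start,end Dates (inclusive); `end` must be after `start`.
#' @param cadence Sampling interval in minutes; must divide 60.
#' @param mean_air_temp,seasonal_amplitude,diurnal_amplitude degC.
#' @param air_noise_sd Stationary SD of the AR(1) air-temperature noise (degC).
#' @param air_noise_persistence AR(1) e-folding time of air noise (hours).
#' @param cloud_persistence AR(1) e-folding time of cloud transmission (hours).
#' @param wind_median,wind_log_sd,wind_persistence Lognormal AR wind process
#'   (m/s, log-SD, hours).
#' @param wave_median,wave_log_sd,wave_persistence Same for significant wave
#'   height (m).
#' @param tide_mean Mean tide level (m above MLLW).
#' @param tidal_constituents List of `c(amplitude_m, period_h, phase_rad)`
#'   harmonic constituents.
#' @param mean_sst,sst_seasonal_amplitude Sea-surface temperature seasonal
#'   cycle (degC).
#' @param microsite_offset_sd SD of the constant per-logger microsite offset
#'   (degC).
#' @param splash_rate Probability per emersed hour of a wave-splash reset;
#'   in \[0, 1\].
#' @param instrument_noise_sd SD of i.i.d. logger noise (degC).
#' @param runup_coefficient Coefficient of the linear wave run-up proxy.
#' @param truth_model Model generating the emersed "true" body temperature:
#'   `"heat_budget"` (default), `"air_proxy"` or `"elvin_gonor"`.
#' @param heat_budget A [heat_budget_params()] list for the truth model.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             start = as.Date("2003-06-01"),
                             end = as.Date("2003-08-31"),
                             cadence = 10,
                             mean_air_temp = 14,
                             seasonal_amplitude = 6,
                             diurnal_amplitude = 4,
                             air_noise_sd = 1.5,
                             air_noise_persistence = 3,
                             cloud_persistence = 6,
                             wind_median = 3,
                             wind_log_sd = 0.5,
                             wind_persistence = 3,
                             wave_median = 1,
                             wave_log_sd = 0.4,
                             wave_persistence = 6,
                             tide_mean = 1.2,
                             tidal_constituents = list(c(1.0, 12.4206, 0),
                                                       c(0.4, 23.9345, 1.0),
                                                       c(0.2, 12.0, 2.0)),
                             mean_sst = 12,
                             sst_seasonal_amplitude = 3,
                             microsite_offset_sd = 2,
                             splash_rate = 0.05,
                             instrument_noise_sd = 2,
                             runup_coefficient = 1,
                             truth_model = c("heat_budget", "air_proxy",
                                             "elvin_gonor"),
                             heat_budget = heat_budget_params()) {
  start <- as.Date(start); end <- as.Date(end)
  if (60 %% cadence != 0) stop("`cadence` must divide 60 minutes")
  if (!(end > start)) stop("empty date range: `end` must be after `start`")
  if (splash_rate < 0 || splash_rate > 1) stop("splash_rate must be in [0, 1]")
  amps <- c(seasonal_amplitude, diurnal_amplitude, air_noise_sd,
            sst_seasonal_amplitude, microsite_offset_sd, instrument_noise_sd)
  if (any(amps < 0)) stop("amplitudes and noise SDs must be >= 0")
  structure(list(seed = as.integer(seed), start = start, end = end,
                 cadence = cadence, mean_air_temp = mean_air_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 air_noise_sd = air_noise_sd,
                 air_noise_persistence = air_noise_persistence,
                 cloud_persistence = cloud_persistence,
                 wind_median = wind_median, wind_log_sd = wind_log_sd,
                 wind_persistence = wind_persistence,
                 wave_median = wave_median, wave_log_sd = wave_log_sd,
                 wave_persistence = wave_persistence,
                 tide_mean = tide_mean,
                 tidal_constituents = tidal_constituents,
                 mean_sst = mean_sst,
                 sst_seasonal_amplitude = sst_seasonal_amplitude,
                 microsite_offset_sd = microsite_offset_sd,
                 splash_rate = splash_rate,
                 instrument_noise_sd = instrument_noise_sd,
                 runup_coefficient = runup_coefficient,
                 truth_model = match.arg(truth_model),
                 heat_budget = heat_budget),
            class = "generator_config")
}

# stationary standard-normal AR(1) driven by pre-drawn innovations
ar1_series <- function(z, phi) {
  x <- numeric(length(z))
  x[1] <- z[1]
  scale <- sqrt(1 - phi^2)
  for (t in seq_along(z)[-1]) x[t] <- phi * x[t - 1] + scale * z[t]
  x
}

#' Generate synthetic environmental forcing
#'
#' Deterministic for a fixed `(site, cfg)`: all randomness comes from one
#' generator seeded with `cfg$seed`, with a fixed draw order (air innovations,
#' then cloud, wind, wave). Shortwave irradiance is exactly zero whenever
#' apparent solar elevation is at or below the horizon.
#'
#' @param site A [site_config()].
#' @param cfg A [generator_config()].
#' @return A tibble with columns `time` (UTC POSIXct at the configured
#'   cadence), `air_temp`, `solar`, `wind`, `sig_wave_height`, `tide_height`,
#'   `sst`; no missing values.
#' @export
generate_environment <- function(site, cfg) {
  stopifnot(inherits(site, "site_config"), inherits(cfg, "generator_config"))
  step <- cfg$cadence * 60
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(cfg$end, "00:00:00"), tz = "UTC") + 86400 - step
  time <- seq(t0, t1, by = step)
  n <- length(time)
  dt_h <- cfg$cadence / 60

  set.seed(cfg$seed)
  z_air <- stats::rnorm(n)
  z_cloud <- stats::rnorm(n)
  z_wind <- stats::rnorm(n)
  z_wave <- stats::rnorm(n)

  lt <- as.POSIXlt(time + site$utc_offset * 3600, tz = "UTC")
  doy <- lt$yday + 1
  local_hour <- lt$hour + lt$min / 60

  seasonal <- cfg$seasonal_amplitude * cos(2 * pi * (doy - 200) / 365.25)
  diurnal <- cfg$diurnal_amplitude * cos(2 * pi * (local_hour - 15) / 24)
  air_noise <- cfg$air_noise_sd *
    ar1_series(z_air, exp(-dt_h / cfg$air_noise_persistence))
  air_temp <- cfg$mean_air_temp + seasonal + diurnal + air_noise

  elev <- solar_elevation(time, site$latitude, site$longitude)
  clear_sky <- ifelse(elev > 0, 1000 * sin(elev * pi / 180), 0)
  cloud <- stats::pnorm(ar1_series(z_cloud, exp(-dt_h / cfg$cloud_persistence)))
  transmission <- 0.35 + 0.65 * cloud
  solar <- clear_sky * transmission

  wind <- exp(log(cfg$wind_median) + cfg$wind_log_sd *
                ar1_series(z_wind, exp(-dt_h / cfg$wind_persistence)))
  wave <- exp(log(cfg$wave_median) + cfg$wave_log_sd *
                ar1_series(z_wave, exp(-dt_h / cfg$wave_persistence)))

  hours_since <- as.numeric(time - t0, units = "hours")
  tide <- rep(cfg$tide_mean, n)
  for (con in cfg$tidal_constituents) {
    tide <- tide + con[1] * cos(2 * pi * hours_since / con[2] + con[3])
  }

  sst <- cfg$mean_sst +
    cfg$sst_seasonal_amplitude * cos(2 * pi * (doy - 230) / 365.25)

  tibble::tibble(time = time, air_temp = air_temp, solar = solar,
                 wind = wind, sig_wave_height = wave, tide_height = tide,
                 sst = sst)
}

#' Generate "true" multi-logger body-temperature records
#'
#' Builds one synthetic biomimetic-logger record per configured logger.
#' During emersion (tide + run-up below logger elevation) the true body
#' temperature follows the configured truth model (steady-state heat budget
#' by default) plus a constant per-logger microsite offset; during submersion
#' it relaxes to sea-surface temperature. Random wave-splash events reset an
#' emersed logger to SST for that instant, with per-instant probability
#' `splash_rate` per hour inflated as the effective water line approaches the
#' logger. I.i.d. instrument noise is added last. Each logger draws from its
#' own substream (`cfg$seed + 7919 * logger_index`), and splash uniforms are
#' drawn regardless of `splash_rate` so that raising the rate only ever adds
#' splashes.
#'
#' @param env An environment tibble from [generate_environment()].
#' @param site A [site_config()].
#' @param cfg A [generator_config()].
#' @return A named list of tibbles (one per logger) with columns `time`,
#'   `body_temp`, `site_id`, `microsite_id`, `source = "observed"`.
#' @export
generate_truth_loggers <- function(env, site, cfg) {
  stopifnot(inherits(site, "site_config"), inherits(cfg, "generator_config"))
  if (site$n_loggers < 1) stop("n_loggers must be >= 1")
  n <- nrow(env)
  dt_h <- cfg$cadence / 60
  runup <- wave_runup(env$sig_wave_height, site$shore_slope,
                      cfg$runup_coefficient)
  water <- env$tide_height + runup
  emersed <- emersion_mask(env$tide_height, runup, site$logger_elevation)

  base <- switch(cfg$truth_model,
    heat_budget = steady_state_temperature(env$air_temp, env$solar, env$wind,
                                           cfg$heat_budget),
    air_proxy = predict_air_proxy(env$air_temp),
    elvin_gonor = predict_elvin_gonor(env$air_temp, env$solar))

  gap <- pmax(site$logger_elevation - water, 0)
  p_splash <- pmin(1, cfg$splash_rate * dt_h * (1 + 3 * exp(-gap / 0.5)))

  loggers <- list()
  for (i in seq_len(site$n_loggers)) {
    set.seed(cfg$seed + 7919L * i)
    offset <- stats::rnorm(1, 0, cfg$microsite_offset_sd)
    u_splash <- stats::runif(n)
    noise <- stats::rnorm(n, 0, cfg$instrument_noise_sd)
    body <- ifelse(emersed, base + offset, env$sst)
    splashed <- emersed & (u_splash < p_splash)
    body[splashed] <- env$sst[splashed]
    body <- body + noise
    id <- sprintf("%s_logger%d", site$site_id, i)
    loggers[[id]] <- tibble::tibble(time = env$time, body_temp = body,
                                    site_id = site$site_id, microsite_id = id,
                                    source = "observed")
  }
  loggers
}
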