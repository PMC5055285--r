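quick_cfg <- function(seed = 7, ...) {
  generator_config(seed = seed, start = as.Date("2003-06-01"),
                   end = as.Date("2003-06-14"), cadence = 60, ...)
}

test_that("generation is bit-identical for a fixed seed and rejects bad configs", {
  site <- site_config()
  e1 <- generate_environment(site, quick_cfg())
  e2 <- generate_environment(site, quick_cfg())
  expect_identical(e1, e2)
  expect_false(identical(e1, generate_environment(site,
                                                  quick_cfg(seed = 8))))
  expect_error(generator_config(cadence = 7), "divide")
  expect_error(generator_config(start = as.Date("2003-06-02"),
                                end = as.Date("2003-06-02")), "empty date range")
  expect_error(generator_config(splash_rate = 1.5), "splash_rate")
  expect_error(site_config(latitude = 100), "latitude")
  expect_error(site_config(n_loggers = 0), "n_loggers")
})

test_that("solar is zero whenever the sun is below the horizon and never negative", {
  site <- site_config()
  env <- generate_environment(site, quick_cfg())
  elev <- solar_elevation(env$time, site$latitude, site$longitude)
  expect_true(all(env$solar[elev <= 0] == 0))
  expect_true(all(env$solar >= 0))
  expect_true(any(elev <= 0) && any(elev > 0))  # both regimes exercised
  expect_false(anyNA(env))
  expect_true(all(env$sig_wave_height >= 0) && all(env$wind >= 0))
  expect_true(all(diff(as.numeric(env$time)) == 3600))
})

test_that("a single harmonic constituent reproduces the closed-form sinusoid", {
  site <- site_config()
  cfg <- quick_cfg(tide_mean = 0,
                   tidal_constituents = list(c(1, 12.42, 0)))
  env <- generate_environment(site, cfg)
  hours <- as.numeric(env$time - env$time[1], units = "hours")
  expect_equal(env$tide_height, cos(2 * pi * hours / 12.42))
  # amplitude 1 m -> range exactly 2 m (the 12.42 h period is well sampled
  # over two weeks of hourly data)
  expect_equal(diff(range(env$tide_height)), 2, tolerance = 1e-3)
})

test_that("with noise, splash and offsets disabled all loggers equal the heat budget", {
  site <- site_config(n_loggers = 3)
  cfg <- quick_cfg(microsite_offset_sd = 0, splash_rate = 0,
                   instrument_noise_sd = 0)
  env <- generate_environment(site, cfg)
  loggers <- generate_truth_loggers(env, site, cfg)
  expect_identical(loggers[[1]]$body_temp, loggers[[2]]$body_temp)
  expect_identical(loggers[[2]]$body_temp, loggers[[3]]$body_temp)

  runup <- wave_runup(env$sig_wave_height, site$shore_slope, 1)
  emersed <- emersion_mask(env$tide_height, runup, site$logger_elevation)
  hb <- steady_state_temperature(env$air_temp, env$solar, env$wind,
                                 cfg$heat_budget)
  expect_equal(loggers[[1]]$body_temp[emersed], hb[emersed])
  # submerged instants sit at SST exactly (noise is off)
  expect_equal(loggers[[1]]$body_temp[!emersed], env$sst[!emersed])
})

test_that("logger generation is deterministic per (seed, logger index)", {
  site <- site_config(n_loggers = 2)
  cfg <- quick_cfg()
  env <- generate_environment(site, cfg)
  l1 <- generate_truth_loggers(env, site, cfg)
  l2 <- generate_truth_loggers(env, site, cfg)
  expect_identical(l1, l2)
  # the first logger of a 1-logger deployment equals the first of 2
  site1 <- site_config(n_loggers = 1)
  l3 <- generate_truth_loggers(env, site1, cfg)
  expect_identical(l3[[1]]$body_temp, l1[[1]]$body_temp)
})

test_that("raising the splash rate cannot raise emersed daily maxima", {
  # heat-stress scenario: SST well below air temperature, so a splash always
  # relaxes the logger toward cooler water
  site <- site_config(n_loggers = 1)
  base_args <- list(mean_air_temp = 20, mean_sst = 10,
                    instrument_noise_sd = 0)
  cfg0 <- do.call(quick_cfg, c(base_args, splash_rate = 0))
  cfg1 <- do.call(quick_cfg, c(base_args, splash_rate = 0.6))
  env <- generate_environment(site, cfg0)
  b0 <- generate_truth_loggers(env, site, cfg0)[[1]]$body_temp
  b1 <- generate_truth_loggers(env, site, cfg1)[[1]]$body_temp
  expect_true(all(b1 <= b0 + 1e-12))
  expect_true(any(b1 < b0))  # some splashes actually occurred
})

test_that("inter-logger spread of daily maxima sits in the field-observed 2-3 degC band", {
  # five loggers per site, one synthetic summer per seed; the statistic is
  # averaged over three seeds to damp the realization noise of drawing only
  # five microsite offsets
  site <- site_config(n_loggers = 5)
  per_seed <- vapply(1:3, function(seed) {
    cfg <- generator_config(seed = seed)
    env <- generate_environment(site, cfg)
    loggers <- generate_truth_loggers(env, site, cfg)
    lh <- lapply(loggers, function(l) hourly_average(l$time, l$body_temp))
    tide_h <- hourly_average(env$time, env$tide_height)$value
    runup_h <- wave_runup(hourly_average(env$time, env$sig_wave_height)$value,
                          site$shore_slope, 1)
    emersed <- emersion_mask(tide_h, runup_h, site$logger_elevation)
    dm <- lapply(lh, function(l)
      daily_max_pairs(l$time, l$value, l$value, emersed, site$utc_offset))
    difs <- c()
    for (i in 1:4) for (j in (i + 1):5) {
      m <- merge(dm[[i]][, c("date", "observed_max")],
                 dm[[j]][, c("date", "observed_max")], by = "date")
      difs <- c(difs, abs(m$observed_max.x - m$observed_max.y))
    }
    mean(difs)
  }, numeric(1))
  expect_gt(mean(per_seed), 2)
  expect_lt(mean(per_seed), 3)
})

test_that("truth can be generated by the simpler models too", {
  site <- site_config(n_loggers = 1)
  cfg <- quick_cfg(truth_model = "air_proxy", microsite_offset_sd = 0,
                   splash_rate = 0, instrument_noise_sd = 0)
  env <- generate_environment(site, cfg)
  runup <- wave_runup(env$sig_wave_height, site$shore_slope, 1)
  emersed <- emersion_mask(env$tide_height, runup, site$logger_elevation)
  lg <- generate_truth_loggers(env, site, cfg)[[1]]
  expect_equal(lg$body_temp[emersed], env$air_temp[emersed])
})
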