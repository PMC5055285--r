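#' @importFrom rlang .data
NULL

#' Hourly averages of a timestamped series
#'
#' For sub-hourly records, each clock hour gets the arithmetic mean of the
#' samples falling in it; hours with no samples are simply absent. For
#' on-the-hour point measurements (exact hourly cadence), each observation is
#' averaged with the following observation to give the mean for the hour it
#' opens, so the final point yields no hour.
#'
#' @param time POSIXct timestamps (UTC), strictly increasing.
#' @param value Numeric values aligned with `time`.
#' @param point_values `"auto"` (default) applies the pairwise rule exactly
#'   when the input sits on the hour at hourly cadence; `"never"` treats the
#'   input as block samples (so averaging already-hourly means is a no-op);
#'   `"always"` forces the pairwise rule.
#' @return A tibble with columns `time` (hour start, UTC) and `value`.
#' @export
hourly_average <- function(time, value,
                           point_values = c("auto", "never", "always")) {
  point_values <- match.arg(point_values)
  stopifnot(length(time) == length(value))
  if (length(time) == 0L) {
    return(tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                          value = numeric()))
  }
  if (is.unsorted(as.numeric(time), strictly = TRUE)) {
    stop("`time` must be strictly increasing")
  }
  dt <- diff(as.numeric(time))
  on_hour <- length(dt) > 0 && all(dt == 3600) &&
    all(as.POSIXlt(time, tz = "UTC")$min == 0)
  if (point_values == "always" || (point_values == "auto" && on_hour)) {
    # on-the-hour point values: pairwise average with the following point
    n <- length(value)
    return(tibble::tibble(time = time[-n],
                          value = (value[-n] + value[-1]) / 2))
  }
  hour <- as.POSIXct(floor(as.numeric(time) / 3600) * 3600,
                     origin = "1970-01-01", tz = "UTC")
  tibble::tibble(hour = hour, value = value) |>
    dplyr::group_by(time = .data$hour) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))
}

#' Solar elevation angle
#'
#' Apparent solar elevation from standard solar geometry: declination from
#' day of year, hour angle from longitude-corrected solar time. Accuracy of a
#' degree or two, ample for night masking and clear-sky shapes.
#'
#' @param time POSIXct instants (UTC).
#' @param latitude,longitude Site coordinates in decimal degrees.
#' @return Elevation in degrees (negative below the horizon).
#' @export
solar_elevation <- function(time, latitude, longitude) {
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  frac_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  decl <- 23.44 * sin(2 * pi * (284 + doy) / 365.25) * pi / 180
  solar_hour <- (frac_hour + longitude / 15) %% 24
  hour_angle <- (solar_hour - 12) * 15 * pi / 180
  phi <- latitude * pi / 180
  sin_el <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hour_angle)
  asin(pmin(pmax(sin_el, -1), 1)) * 180 / pi
}

#' Fill a daytime-window solar record to a complete hourly series
#'
#' Gridded shortwave products are often limited to 09:00-16:00 local standard
#' time. This fills each local day: hours with solar elevation <= 0 are set
#' to zero; the gaps between sunrise and 09:00 and between 16:00 and sunset
#' are linearly interpolated between the window boundary value and zero at
#' the sunrise/sunset hour. Values inside the window pass through unchanged.
#' Days whose 09:00 or 16:00 boundary value is missing cannot be filled and
#' are flagged.
#'
#' @param time Hourly POSIXct timestamps (UTC) covering whole days.
#' @param solar Hourly shortwave irradiance (W/m^2) with NAs outside the
#'   daytime window.
#' @param elevation Solar elevation (degrees) aligned with `time`.
#' @param utc_offset Hours to add to UTC for local standard time.
#' @return A tibble with columns `time`, `solar` (filled) and `flagged`
#'   (logical, TRUE for hours on days whose fill was undefined).
#' @export
fill_solar <- function(time, solar, elevation, utc_offset = 0) {
  stopifnot(length(time) == length(solar), length(time) == length(elevation))
  local <- time + utc_offset * 3600
  lt <- as.POSIXlt(local, tz = "UTC")
  date <- as.Date(local, tz = "UTC")
  hour <- lt$hour
  out <- solar
  out[elevation <= 0] <- 0
  flagged <- rep(FALSE, length(time))
  tnum <- as.numeric(time)

  for (d in unique(date)) {
    idx <- which(date == d)
    day_hour <- hour[idx]
    day_el <- elevation[idx]
    # morning gap: sunrise anchor is the last hour at or before which the sun
    # is still down; interpolate up to the 09:00 boundary value
    i9 <- idx[day_hour == 9]
    morning <- idx[day_hour < 9 & day_el > 0 & is.na(out[idx])]
    if (length(morning) > 0) {
      rise <- idx[day_hour < 9 & day_el <= 0]
      if (length(i9) == 1 && !is.na(out[i9]) && length(rise) > 0) {
        t0 <- max(tnum[rise])
        out[morning] <- out[i9] * (tnum[morning] - t0) / (tnum[i9] - t0)
      } else {
        flagged[idx] <- TRUE
      }
    }
    # evening gap: zero anchor at the first hour after 16:00 with the sun down
    i16 <- idx[day_hour == 16]
    evening <- idx[day_hour > 16 & day_el > 0 & is.na(out[idx])]
    if (length(evening) > 0) {
      set <- idx[day_hour > 16 & day_el <= 0]
      if (length(i16) == 1 && !is.na(out[i16]) && length(set) > 0) {
        t1 <- min(tnum[set])
        out[evening] <- out[i16] * (t1 - tnum[evening]) / (t1 - tnum[i16])
      } else {
        flagged[idx] <- TRUE
      }
    }
    # anything still missing inside the day means the window block itself had
    # holes; the day's fill is undefined
    if (anyNA(out[idx])) flagged[idx] <- TRUE
  }
  tibble::tibble(time = time, solar = out, flagged = flagged)
}

#' Wave run-up (swash) proxy
#'
#' Linear proxy for the vertical run-up of waves above still tide level:
#' `runup = coefficient * shore_slope * sig_wave_height`. Added to still tide
#' height before comparing against logger elevation.
#'
#' @param sig_wave_height Significant wave height (m), >= 0.
#' @param shore_slope Dimensionless shore slope (rise/run), >= 0.
#' @param coefficient Dimensionless tuning coefficient, default 1.
#' @return Run-up in metres.
#' @export
wave_runup <- function(sig_wave_height, shore_slope, coefficient = 1) {
  if (any(sig_wave_height < 0, na.rm = TRUE) || any(shore_slope < 0) ||
      any(coefficient < 0)) {
    stop("wave run-up inputs must be non-negative")
  }
  coefficient * shore_slope * sig_wave_height
}

#' Emersion mask from effective water level
#'
#' A logger is emersed (exposed to air) when still tide height plus wave
#' run-up is strictly below its elevation; equality counts as submerged.
#'
#' @param tide_height Tide height (m above MLLW).
#' @param runup Wave run-up (m), aligned with `tide_height`.
#' @param logger_elevation Logger elevation (m above MLLW).
#' @return Logical vector, TRUE when emersed.
#' @export
emersion_mask <- function(tide_height, runup, logger_elevation) {
  n <- max(length(tide_height), length(runup))
  if ((length(runup) != 1L && length(runup) != n) ||
      (length(tide_height) != 1L && length(tide_height) != n)) {
    stop("`runup` must align with `tide_height`")
  }
  (tide_height + runup) < logger_elevation
}

#' Paired daily maximum temperatures during emersion
#'
#' For each site-local calendar day, takes the highest hourly value over
#' emersed hours separately for the forecast and the observed series (the
#' hour of the maximum need not match). Days on which either side has no
#' emersed finite value are dropped.
#'
#' @param time Hourly POSIXct timestamps (UTC).
#' @param forecast,observed Hourly temperature series (degrees Celsius)
#'   aligned with `time`; NAs allowed.
#' @param emersed Logical emersion mask aligned with `time`.
#' @param utc_offset Hours to add to UTC for the site-local day (standard
#'   time, no daylight saving).
#' @return A tibble with columns `date`, `forecast_max`, `observed_max`.
#' @export
daily_max_pairs <- function(time, forecast, observed, emersed, utc_offset = 0) {
  n <- length(time)
  if (length(forecast) != n || length(observed) != n || length(emersed) != n) {
    stop("forecast, observed and emersed must align with `time`")
  }
  date <- as.Date(time + utc_offset * 3600, tz = "UTC")
  keep <- emersed & !is.na(emersed)
  tibble::tibble(date = date[keep],
                 forecast = forecast[keep],
                 observed = observed[keep]) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      forecast_max = if (any(is.finite(.data$forecast)))
        max(.data$forecast[is.finite(.data$forecast)]) else NA_real_,
      observed_max = if (any(is.finite(.data$observed)))
        max(.data$observed[is.finite(.data$observed)]) else NA_real_,
      .groups = "drop") |>
    dplyr::filter(is.finite(.data$forecast_max), is.finite(.data$observed_max))
}
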