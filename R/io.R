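#' Write a timestamped series to CSV
#'
#' Timestamps are written as ISO-8601 UTC (`2003-06-01T00:00:00Z`) in a
#' `time` column followed by the value columns; a header row is always
#' written. The same dialect is read back by [read_series_csv()].
#'
#' @param series A tibble whose first column `time` is POSIXct (UTC).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(is.data.frame(series), "time" %in% names(series))
  out <- series
  out$time <- format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a timestamped series CSV
#'
#' Counterpart of [write_series_csv()]: parses the `time` column as UTC
#' POSIXct and leaves other columns as read.
#'
#' @param path CSV file path.
#' @return A tibble with a POSIXct `time` column.
#' @export
read_series_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot("time" %in% names(x))
  if (!inherits(x$time, "POSIXct")) {
    x$time <- as.POSIXct(x$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  } else {
    attr(x$time, "tzone") <- "UTC"
  }
  x
}

#' Read an NDBC standard meteorological text file
#'
#' Parses the whitespace-delimited buoy format: two header lines (column
#' names prefixed with `#`, then units), then one row per observation.
#' Sentinel missing values (99.0, 999, 9999 and their decimal variants) are
#' mapped to NA. Files without a minutes column (older years) are accepted.
#'
#' @param path Path to an NDBC realtime/standard meteorological file.
#' @return A tibble with columns `time` (UTC), `wind` (WSPD, m/s),
#'   `sig_wave_height` (WVHT, m), `air_temp` (ATMP, degC), `sst` (WTMP,
#'   degC); unrecognised columns are kept under their NDBC names.
#' @export
read_ndbc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("NDBC file too short")
  header <- strsplit(sub("^#", "", lines[1]), "\\s+")[[1]]
  header <- header[nzchar(header)]
  body <- lines[-(1:2)]
  dat <- utils::read.table(text = body, col.names = header,
                           stringsAsFactors = FALSE)
  for (nm in names(dat)) {
    v <- dat[[nm]]
    if (is.numeric(v) && !nm %in% c("YY", "YYYY", "MM", "DD", "hh", "mm")) {
      v[v %in% c(99, 999, 9999) | abs(v - 99) < 1e-9 | abs(v - 999) < 1e-9] <- NA
      dat[[nm]] <- v
    }
  }
  year <- if ("YYYY" %in% names(dat)) dat$YYYY else {
    y <- dat$YY
    ifelse(y < 100, ifelse(y > 50, 1900 + y, 2000 + y), y)
  }
  minute <- if ("mm" %in% names(dat)) dat$mm else 0
  time <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:00",
                             year, dat$MM, dat$DD, dat$hh, minute),
                     tz = "UTC")
  out <- tibble::tibble(time = time,
                        wind = dat[["WSPD"]],
                        sig_wave_height = dat[["WVHT"]],
                        air_temp = dat[["ATMP"]],
                        sst = dat[["WTMP"]])
  extra <- setdiff(names(dat),
                   c("YY", "YYYY", "MM", "DD", "hh", "mm",
                     "WSPD", "WVHT", "ATMP", "WTMP"))
  for (nm in extra) out[[nm]] <- dat[[nm]]
  out
}

#' Read a CO-OPS-style tide CSV
#'
#' Expects a header row and at least two columns: a timestamp and a water
#' level in metres above MLLW; extra columns are ignored.
#'
#' @param path CSV file path.
#' @return A tibble with columns `time` (UTC) and `tide_height` (m).
#' @export
read_coops_tide <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(x) < 2L) stop("tide CSV needs a timestamp and a water-level column")
  time <- x[[1]]
  if (!inherits(time, "POSIXct")) {
    time <- as.POSIXct(time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                      "%Y-%m-%d %H:%M", "%Y-%m-%d %H:%M:%S"))
  } else {
    attr(time, "tzone") <- "UTC"
  }
  tibble::tibble(time = time, tide_height = as.numeric(x[[2]]))
}

#' Write a contingency table as CSV
#'
#' Rows are forecast categories, columns observed categories; the first
#' column holds the forecast labels for audit.
#'
#' @param tab A `contingency_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path) {
  df <- as.data.frame(unclass(tab))
  df <- cbind(forecast = rownames(df), df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
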