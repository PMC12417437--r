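# CSV interchange. Timestamps are written as ISO 8601 UTC
# ("2021-09-01T00:15:00Z") and measurements with a fixed number of decimals
# (far below instrument resolution) so writer/reader pairs round-trip
# bit-identically.

iso_ts <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

num6 <- function(x) sprintf("%.6f", x)

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # column presence is validated by the callers; silence readr's complaint
  # about typed parsers for columns a malformed file lacks
  suppressWarnings(readr::read_csv(path, col_types = col_types, progress = FALSE))
}

#' Read and write sensor CSVs
#'
#' Sensor files have columns `timestamp` (ISO 8601), `site`, `pm25_ugm3`.
#' Reading parses, sorts per site and collapses duplicate (site, timestamp)
#' rows with equal values (with a warning); duplicates with conflicting
#' values are an error, as are unparseable timestamps and negative
#' concentrations (reported with their row numbers).
#'
#' @param path CSV file path.
#' @param series Tibble (`timestamp`, `site`, `pm25_ugm3`).
#'
#' @return `read_sensor_csv()` returns the parsed tibble;
#'   `write_sensor_csv()` returns `path` invisibly.
#' @export
read_sensor_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(timestamp = readr::col_character(),
                                         site = readr::col_character(),
                                         pm25_ugm3 = readr::col_double()))
  stopifnot_columns(df, c("timestamp", "site", "pm25_ugm3"), basename(path))
  ts <- suppressWarnings(lubridate::ymd_hms(df$timestamp, tz = "UTC", truncated = 3))
  if (anyNA(ts)) {
    stop("unparseable timestamp at row(s): ",
         paste(head(which(is.na(ts)), 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$pm25_ugm3) || any(df$pm25_ugm3 < 0)) {
    bad <- which(is.na(df$pm25_ugm3) | df$pm25_ugm3 < 0)
    stop("missing or negative pm25_ugm3 at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$timestamp <- ts
  dup <- duplicated(df[c("site", "timestamp")])
  if (any(dup)) {
    resolved <- df |>
      dplyr::distinct(.data$site, .data$timestamp, .data$pm25_ugm3)
    if (anyDuplicated(resolved[c("site", "timestamp")])) {
      stop("duplicate (site, timestamp) rows with conflicting values", call. = FALSE)
    }
    warning("collapsed ", sum(dup), " duplicate (site, timestamp) row(s)",
            call. = FALSE)
    df <- resolved
  }
  dplyr::arrange(df, .data$site, .data$timestamp)
}

#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(series, path) {
  stopifnot_columns(series, c("timestamp", "site", "pm25_ugm3"), "series")
  out <- dplyr::mutate(series, timestamp = iso_ts(.data$timestamp),
                       pm25_ugm3 = num6(.data$pm25_ugm3))
  readr::write_csv(out[c("timestamp", "site", "pm25_ugm3")], path, progress = FALSE)
  invisible(path)
}

#' Read and write meteorology CSVs
#'
#' Columns `timestamp` (ISO 8601), `temp_c`, `rh_pct` (0-100).
#'
#' @param path CSV file path.
#' @param met Tibble (`timestamp`, `temp_c`, `rh_pct`).
#'
#' @return The parsed tibble / `path` invisibly.
#' @export
read_met_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(timestamp = readr::col_character(),
                                         temp_c = readr::col_double(),
                                         rh_pct = readr::col_double()))
  stopifnot_columns(df, c("timestamp", "temp_c", "rh_pct"), basename(path))
  df$timestamp <- as_utc(df$timestamp)
  if (any(df$rh_pct < 0 | df$rh_pct > 100, na.rm = TRUE)) {
    stop("rh_pct outside [0, 100]", call. = FALSE)
  }
  dplyr::arrange(df, .data$timestamp)
}

#' @rdname read_met_csv
#' @export
write_met_csv <- function(met, path) {
  stopifnot_columns(met, c("timestamp", "temp_c", "rh_pct"), "met")
  out <- dplyr::mutate(met, timestamp = iso_ts(.data$timestamp),
                       temp_c = num6(.data$temp_c), rh_pct = num6(.data$rh_pct))
  readr::write_csv(out[c("timestamp", "temp_c", "rh_pct")], path, progress = FALSE)
  invisible(path)
}

#' Read and write diffusion-tube CSVs
#'
#' Columns `location`, `deploy_start`, `deploy_end` (ISO 8601), `tube_id`,
#' `no2_ugm3`, and optionally `period`.
#'
#' @param path CSV file path.
#' @param tubes Tibble of tube records.
#'
#' @return The parsed tibble / `path` invisibly.
#' @export
read_tube_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(.default = readr::col_guess(),
                                         location = readr::col_character(),
                                         deploy_start = readr::col_character(),
                                         deploy_end = readr::col_character(),
                                         no2_ugm3 = readr::col_double()))
  stopifnot_columns(df, c("location", "deploy_start", "deploy_end", "no2_ugm3"),
                    basename(path))
  df$deploy_start <- as_utc(df$deploy_start)
  df$deploy_end <- as_utc(df$deploy_end)
  if (any(df$no2_ugm3 <= 0, na.rm = TRUE) || anyNA(df$no2_ugm3)) {
    stop("no2_ugm3 must be present and > 0", call. = FALSE)
  }
  dplyr::arrange(df, .data$location, .data$deploy_start)
}

#' @rdname read_tube_csv
#' @export
write_tube_csv <- function(tubes, path) {
  stopifnot_columns(tubes, c("location", "deploy_start", "deploy_end", "no2_ugm3"),
                    "tubes")
  out <- tubes |>
    dplyr::mutate(deploy_start = iso_ts(.data$deploy_start),
                  deploy_end = iso_ts(.data$deploy_end),
                  no2_ugm3 = num6(.data$no2_ugm3))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write validated hourly CSVs
#'
#' Columns `hour_start` (ISO 8601), `site`, `pm25_ugm3`, `n_readings`,
#' `status`.
#'
#' @param path CSV file path.
#' @param hourly Validated hourly tibble.
#'
#' @return The parsed tibble / `path` invisibly.
#' @export
read_validated_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(hour_start = readr::col_character(),
                                         site = readr::col_character(),
                                         pm25_ugm3 = readr::col_double(),
                                         n_readings = readr::col_integer(),
                                         status = readr::col_character()))
  stopifnot_columns(df, c("hour_start", "site", "pm25_ugm3", "n_readings", "status"),
                    basename(path))
  df$hour_start <- as_utc(df$hour_start)
  bad <- setdiff(unique(df$status), qc_statuses)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  df |>
    dplyr::select("site", "hour_start", "pm25_ugm3", "n_readings", "status") |>
    dplyr::arrange(.data$site, .data$hour_start)
}

#' @rdname read_validated_csv
#' @export
write_validated_csv <- function(hourly, path) {
  stopifnot_columns(hourly, c("site", "hour_start", "pm25_ugm3", "n_readings", "status"),
                    "hourly")
  out <- dplyr::mutate(hourly, hour_start = iso_ts(.data$hour_start),
                       pm25_ugm3 = num6(.data$pm25_ugm3))
  readr::write_csv(out[c("hour_start", "site", "pm25_ugm3", "n_readings", "status")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read reference-monitor monthly means
#'
#' Columns `month` (first-of-month date, `YYYY-MM-DD`) and `no2_ugm3`.
#'
#' @param path CSV file path.
#'
#' @return A tibble (`month` Date, `no2_ugm3`).
#' @export
read_reference_csv <- function(path) {
  df <- read_csv_quiet(path, readr::cols(month = readr::col_date(),
                                         no2_ugm3 = readr::col_double()))
  stopifnot_columns(df, c("month", "no2_ugm3"), basename(path))
  dplyr::arrange(df, .data$month)
}
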