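#' Validation configuration for the 4-step sensor QC pipeline
#'
#' Houses every threshold of the pipeline: Step 1 completeness (readings per
#' hour, hours per day, days per month), Step 2 meteorology bounds
#' (manufacturer operating envelope), Step 3 static-data window and Step 4
#' MAD outlier exclusion.
#'
#' @param min_readings_per_hour Minimum 15-minute readings for a valid hourly
#'   average (default 3, i.e. 75 percent completeness of a 4-reading hour).
#' @param min_hours_per_day Minimum valid hours for a covered day (default 18).
#' @param min_days_per_month Minimum covered days for a covered month
#'   (default 23).
#' @param temp_low,temp_high Strict temperature bounds, degrees C (defaults
#'   -10 and 35): hours outside `(temp_low, temp_high)` are removed.
#' @param rh_min,rh_max Relative-humidity keep-bounds, percent: hours are kept
#'   when `rh_min < RH < rh_max`. The default (`rh_min = 35`, `rh_max = Inf`)
#'   is the literal manufacturer rule "keep RH > 35 percent"; typical optical
#'   particle counter practice instead masks high humidity, so both bounds
#'   are configurable.
#' @param static_window Number of consecutive valid hourly samples whose zero
#'   moving standard deviation flags static (stuck) data (default 5).
#' @param mad_multiplier Exclusion threshold in MAD units (default 3).
#' @param b MAD scale constant (default 1.4826, the normal-consistency
#'   constant `1 / qnorm(0.75)` rounded to 4 decimals).
#' @param mad_signed If `TRUE`, compute the MAD from signed deviations
#'   (audit-only literal reading of the printed formula; the signed median
#'   deviation is ~0 and the filter degenerates). Default `FALSE`: standard
#'   MAD on absolute deviations.
#' @param reiterate_completeness If `TRUE`, re-apply the day/month coverage
#'   rules after Steps 2-4 (default `FALSE`: single pass in listed order).
#'
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(min_readings_per_hour = 3,
                              min_hours_per_day = 18,
                              min_days_per_month = 23,
                              temp_low = -10,
                              temp_high = 35,
                              rh_min = 35,
                              rh_max = Inf,
                              static_window = 5,
                              mad_multiplier = 3,
                              b = 1.4826,
                              mad_signed = FALSE,
                              reiterate_completeness = FALSE) {
  counts <- c(min_readings_per_hour, min_hours_per_day, min_days_per_month,
              static_window)
  if (any(counts < 1)) stop("count thresholds must be >= 1", call. = FALSE)
  if (temp_low >= temp_high) stop("temp_low must be < temp_high", call. = FALSE)
  if (b <= 0 || mad_multiplier <= 0) stop("b and mad_multiplier must be > 0", call. = FALSE)
  structure(list(
    min_readings_per_hour = as.integer(min_readings_per_hour),
    min_hours_per_day = as.integer(min_hours_per_day),
    min_days_per_month = as.integer(min_days_per_month),
    temp_low = temp_low, temp_high = temp_high,
    rh_min = rh_min, rh_max = rh_max,
    static_window = as.integer(static_window),
    mad_multiplier = mad_multiplier, b = b,
    mad_signed = isTRUE(mad_signed),
    reiterate_completeness = isTRUE(reiterate_completeness)
  ), class = "validation_config")
}

check_raw_series <- function(raw) {
  stopifnot_columns(raw, c("timestamp", "site", "pm25_ugm3"), "raw series")
  if (any(!is.finite(raw$pm25_ugm3)) || any(raw$pm25_ugm3 < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  bad <- raw |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp, strictly = TRUE),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("timestamps must be strictly increasing per site (unsorted or duplicated at: ",
         paste(bad$site, collapse = ", "), ")", call. = FALSE)
  }
  invisible(raw)
}

#' Aggregate 15-minute readings to hourly averages (Step 1, hour rule)
#'
#' One record per clock hour `[h, h+1)` that has at least one reading; the
#' hourly value is the mean over available readings. Hours with fewer than
#' `min_readings_per_hour` readings are flagged `removed_step1_hour`; hours
#' with no readings at all are absent (counted later as missing).
#'
#' @param raw Tibble of raw readings (`timestamp`, `site`, `pm25_ugm3`),
#'   strictly increasing timestamps per site.
#' @param config A [validation_config()].
#'
#' @return An hourly tibble (`site`, `hour_start`, `pm25_ugm3`, `n_readings`,
#'   `status`).
#' @export
aggregate_to_hourly <- function(raw, config = validation_config()) {
  check_raw_series(raw)
  raw |>
    dplyr::mutate(hour_start = lubridate::floor_date(.data$timestamp, "hour")) |>
    dplyr::group_by(.data$site, .data$hour_start) |>
    dplyr::summarise(pm25_ugm3 = mean(.data$pm25_ugm3),
                     n_readings = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(status = ifelse(.data$n_readings >= config$min_readings_per_hour,
                                  "valid", "removed_step1_hour")) |>
    dplyr::arrange(.data$site, .data$hour_start)
}

#' Apply day and month coverage rules (Step 1, day/month rules)
#'
#' A day is covered iff it has at least `min_hours_per_day` currently valid
#' hours; valid hours on uncovered days become `removed_step1_day`. A month
#' is covered iff it has at least `min_days_per_month` covered days; valid
#' hours in uncovered months become `removed_step1_month`.
#'
#' @param hourly Hourly tibble from [aggregate_to_hourly()].
#' @param config A [validation_config()].
#'
#' @return The hourly tibble with updated `status`.
#' @export
apply_completeness <- function(hourly, config = validation_config()) {
  h <- hourly |>
    dplyr::mutate(.date = lubridate::as_date(.data$hour_start))
  day_cover <- h |>
    dplyr::filter(.data$status == "valid") |>
    dplyr::count(.data$site, .data$.date) |>
    dplyr::filter(.data$n >= config$min_hours_per_day) |>
    dplyr::mutate(covered_day = TRUE) |>
    dplyr::select("site", ".date", "covered_day")
  h <- h |>
    dplyr::left_join(day_cover, by = c("site", ".date")) |>
    dplyr::mutate(
      covered_day = dplyr::coalesce(.data$covered_day, FALSE),
      status = ifelse(.data$status == "valid" & !.data$covered_day,
                      "removed_step1_day", .data$status)
    )
  month_cover <- day_cover |>
    dplyr::mutate(.month = lubridate::floor_date(.data$.date, "month")) |>
    dplyr::count(.data$site, .data$.month) |>
    dplyr::filter(.data$n >= config$min_days_per_month) |>
    dplyr::mutate(covered_month = TRUE) |>
    dplyr::select("site", ".month", "covered_month")
  h |>
    dplyr::mutate(.month = lubridate::floor_date(.data$.date, "month")) |>
    dplyr::left_join(month_cover, by = c("site", ".month")) |>
    dplyr::mutate(
      covered_month = dplyr::coalesce(.data$covered_month, FALSE),
      status = ifelse(.data$status == "valid" & !.data$covered_month,
                      "removed_step1_month", .data$status)
    ) |>
    dplyr::select(-".date", -".month", -"covered_day", -"covered_month")
}

#' Apply the meteorology mask (Step 2)
#'
#' Keeps hours whose joined meteorology lies inside the manufacturer
#' operating envelope: `temp_low < t < temp_high` and `rh_min < RH < rh_max`
#' (all strict). Valid hours violating the envelope become `removed_step2`.
#' Hours with no meteorology record are retained: absence of covariate data
#' is not evidence of an envelope violation.
#'
#' @param hourly Hourly tibble.
#' @param met Meteorology tibble (`timestamp`, `temp_c`, `rh_pct`) at hourly
#'   cadence.
#' @param config A [validation_config()].
#'
#' @return The hourly tibble with updated `status`.
#' @export
apply_met_filter <- function(hourly, met, config = validation_config()) {
  stopifnot_columns(met, c("timestamp", "temp_c", "rh_pct"), "meteorology")
  met_h <- met |>
    dplyr::mutate(hour_start = lubridate::floor_date(.data$timestamp, "hour")) |>
    dplyr::distinct(.data$hour_start, .keep_all = TRUE) |>
    dplyr::select("hour_start", "temp_c", "rh_pct")
  hourly |>
    dplyr::left_join(met_h, by = "hour_start") |>
    dplyr::mutate(
      .ok = is.na(.data$temp_c) | is.na(.data$rh_pct) |
        (.data$temp_c > config$temp_low & .data$temp_c < config$temp_high &
           .data$rh_pct > config$rh_min & .data$rh_pct < config$rh_max),
      status = ifelse(.data$status == "valid" & !.data$.ok,
                      "removed_step2", .data$status)
    ) |>
    dplyr::select(-"temp_c", -"rh_pct", -".ok")
}

# Indices belonging to any length-w window of x with zero standard deviation
# (all values identical within tol). Windows slide over x in the order given.
static_window_indices <- function(x, w, tol = 1e-12) {
  n <- length(x)
  if (n < w) return(integer())
  win <- stats::embed(x, w)  # row i = x[i+w-1], ..., x[i]
  flat <- apply(win, 1, max) - apply(win, 1, min) <= tol
  idx <- which(flat)
  if (!length(idx)) return(integer())
  sort(unique(as.integer(outer(idx, 0:(w - 1), `+`))))
}

#' Remove static (stuck-sensor) data (Step 3)
#'
#' Over each site's currently valid hourly samples in time order (gaps
#' ignored), every contiguous window of `static_window` samples with zero
#' standard deviation (all values identical within 1e-12) has all its members
#' flagged `removed_step3`.
#'
#' @param hourly Hourly tibble.
#' @param config A [validation_config()].
#'
#' @return The hourly tibble with updated `status`.
#' @export
apply_static_filter <- function(hourly, config = validation_config()) {
  hourly |>
    dplyr::arrange(.data$site, .data$hour_start) |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(df, key) {
      v <- which(df$status == "valid")
      hit <- static_window_indices(df$pm25_ugm3[v], config$static_window)
      df$status[v[hit]] <- "removed_step3"
      df
    }) |>
    dplyr::ungroup()
}

#' Exclude MAD outliers (Step 4)
#'
#' Per site and calendar month, over the currently valid hourly values `x`:
#' the monthly median is `m = median(x)` and `MAD = b * median(|x - m|)`.
#' Values outside `[m - k * MAD, m + k * MAD]` (with `k = mad_multiplier`)
#' are flagged `removed_step4`. When `MAD = 0` (a constant month) nothing is
#' removed: a literal application would delete every value differing from the
#' median by any amount, and stuck data is Step 3's job.
#'
#' @param hourly Hourly tibble.
#' @param config A [validation_config()].
#'
#' @return The hourly tibble with updated `status`.
#' @export
apply_mad_filter <- function(hourly, config = validation_config()) {
  hourly |>
    dplyr::mutate(.month = lubridate::floor_date(
      lubridate::as_date(.data$hour_start), "month")) |>
    dplyr::group_by(.data$site, .data$.month) |>
    dplyr::group_modify(function(df, key) {
      v <- which(df$status == "valid")
      if (!length(v)) return(df)
      x <- df$pm25_ugm3[v]
      med <- median(x)
      dev <- if (config$mad_signed) x - med else abs(x - med)
      mad_val <- config$b * median(dev)
      if (mad_val > 0) {
        k <- config$mad_multiplier
        out <- x < med - k * mad_val | x > med + k * mad_val
        df$status[v[out]] <- "removed_step4"
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".month")
}

#' Run the full 4-step validation pipeline
#'
#' Applies, exactly once and in order: hourly aggregation with the
#' readings-per-hour rule, day/month coverage, the meteorology mask, the
#' static-data filter and the MAD outlier filter; then computes a
#' data-capture report against the number of clock hours in the analysis
#' period.
#'
#' @param raw Raw readings tibble (`timestamp`, `site`, `pm25_ugm3`).
#' @param met Optional meteorology tibble; if `NULL` Step 2 is skipped.
#' @param config A [validation_config()].
#' @param period_start,period_end Analysis period `[start, end)` defining the
#'   capture denominator; defaults to the span of `raw` rounded to whole
#'   hours.
#'
#' @return An object of class `qc_run`: a list with `hourly` (the validated
#'   hourly tibble) and `report` (the [capture_report()] tibble).
#' @export
#'
#' @examples
#' net <- generate_network(network_config(
#'   n_sites = 2, period_end = "2021-10-01", seed = 3
#' ))
#' qc <- run_qc_pipeline(net$series,
#'   met = generate_meteorology(period_end = "2021-10-01", seed = 3)
#' )
#' glance(qc)
run_qc_pipeline <- function(raw, met = NULL, config = validation_config(),
                            period_start = NULL, period_end = NULL) {
  period_start <- as_utc(period_start %||%
                           lubridate::floor_date(min(raw$timestamp), "hour"))
  period_end <- as_utc(period_end %||%
                         lubridate::ceiling_date(max(raw$timestamp), "hour"))
  hourly <- aggregate_to_hourly(raw, config) |>
    apply_completeness(config)
  if (!is.null(met)) hourly <- apply_met_filter(hourly, met, config)
  hourly <- hourly |>
    apply_static_filter(config) |>
    apply_mad_filter(config)
  if (config$reiterate_completeness) hourly <- apply_completeness(hourly, config)
  report <- capture_report(hourly, period_start, period_end)
  structure(list(hourly = hourly, report = report,
                 period_start = period_start, period_end = period_end,
                 config = config),
            class = "qc_run")
}

#' Data-capture report
#'
#' Accounts for every potential hourly reading in the analysis period:
#' `valid_hours + sum(removed by step) + missing_hours = potential_hours`,
#' and `capture_pct = 100 * valid_hours / potential_hours`.
#'
#' @param hourly Validated hourly tibble.
#' @param period_start,period_end Analysis period `[start, end)`.
#'
#' @return A tibble with one row per site: `potential_hours`, `valid_hours`,
#'   `missing_hours`, one count per removal status, and `capture_pct`.
#' @export
capture_report <- function(hourly, period_start, period_end) {
  potential <- n_clock_hours(period_start, period_end)
  counts <- hourly |>
    dplyr::count(.data$site, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
  for (s in qc_statuses) {
    if (!s %in% names(counts)) counts[[s]] <- 0L
  }
  counts |>
    dplyr::rename(valid_hours = "valid") |>
    dplyr::mutate(
      potential_hours = potential,
      missing_hours = potential - rowSums(dplyr::pick(dplyr::all_of(
        c("valid_hours", setdiff(qc_statuses, "valid"))))),
      capture_pct = 100 * .data$valid_hours / potential
    ) |>
    dplyr::select("site", "potential_hours", "valid_hours", "missing_hours",
                  dplyr::all_of(setdiff(qc_statuses, "valid")), "capture_pct")
}

#' @export
print.qc_run <- function(x, ...) {
  cat("4-step sensor validation run\n")
  cat("  period:", format(x$period_start), "to", format(x$period_end), "(UTC)\n")
  print(x$report)
  invisible(x)
}

#' @rdname run_qc_pipeline
#' @param x A `qc_run` object.
#' @param ... Unused.
#' @method glance qc_run
#' @export
glance.qc_run <- function(x, ...) x$report

#' @rdname run_qc_pipeline
#' @method tidy qc_run
#' @export
tidy.qc_run <- function(x, ...) {
  x$hourly |>
    dplyr::count(.data$site, .data$status, name = "hours")
}
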