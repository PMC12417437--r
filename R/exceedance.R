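#' WHO air-quality guideline set
#'
#' Default limits follow the WHO Global Air Quality Guidelines (2021):
#' PM2.5 annual 5 and 24-h 15 ug/m3; NO2 annual 10 and 24-h 25 ug/m3.
#'
#' @param pollutant `"pm25"` or `"no2"`, or any name when both limits are
#'   given explicitly.
#' @param annual_limit,daily_limit Guideline limits, ug/m3; defaults looked
#'   up from the pollutant name.
#'
#' @return A list of class `guideline_set`.
#' @export
guideline_set <- function(pollutant = "pm25", annual_limit = NULL, daily_limit = NULL) {
  defaults <- list(pm25 = c(annual = 5, daily = 15), no2 = c(annual = 10, daily = 25))
  if (is.null(annual_limit) || is.null(daily_limit)) {
    if (!pollutant %in% names(defaults)) {
      stop("no default guidelines for pollutant '", pollutant,
           "': give annual_limit and daily_limit", call. = FALSE)
    }
    annual_limit <- annual_limit %||% defaults[[pollutant]][["annual"]]
    daily_limit <- daily_limit %||% defaults[[pollutant]][["daily"]]
  }
  if (annual_limit <= 0 || daily_limit <= 0) stop("limits must be > 0", call. = FALSE)
  structure(list(pollutant = pollutant, annual_limit = annual_limit,
                 daily_limit = daily_limit), class = "guideline_set")
}

#' Daily means from validated hourly data
#'
#' Calendar-day mean of valid hours per site. Days with fewer than
#' `min_hours` valid hours are kept in the output but marked not `recorded`,
#' and are excluded from exceedance denominators (reusing the 18-hour
#' day-coverage convention of the validation pipeline).
#'
#' @param hourly Validated hourly tibble (from [run_qc_pipeline()] or the
#'   step functions).
#' @param min_hours Minimum valid hours for a recorded day (default 18).
#'
#' @return A tibble: `site`, `date`, `daily_mean`, `n_valid_hours`,
#'   `recorded`.
#' @export
daily_means <- function(hourly, min_hours = 18) {
  hourly |>
    dplyr::filter(.data$status == "valid") |>
    dplyr::mutate(date = lubridate::as_date(.data$hour_start)) |>
    dplyr::group_by(.data$site, .data$date) |>
    dplyr::summarise(daily_mean = mean(.data$pm25_ugm3),
                     n_valid_hours = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(recorded = .data$n_valid_hours >= min_hours)
}

#' Summary statistics and guideline exceedances per site
#'
#' Mean, max and 95th/25th/median percentiles of valid hourly values (linear
#' interpolation between order statistics), plus the percentage of recorded
#' days whose daily mean strictly exceeds the 24-h guideline and a flag for
#' the annual mean exceeding the annual guideline.
#'
#' @param hourly Validated hourly tibble.
#' @param guidelines A [guideline_set()].
#' @param min_hours Minimum valid hours for a recorded day (default 18).
#'
#' @return A tibble per site: `mean`, `max`, `p95`, `p25`, `median`,
#'   `n_days`, `pct_days_exceeding`, `annual_mean_exceeds`.
#' @export
#'
#' @examples
#' net <- generate_network(network_config(n_sites = 2, period_end = "2021-10-01"))
#' hourly <- aggregate_to_hourly(net$series)
#' exceedance_summary(hourly)
exceedance_summary <- function(hourly, guidelines = guideline_set(),
                               min_hours = 18) {
  valid <- dplyr::filter(hourly, .data$status == "valid")
  if (!nrow(valid)) stop("no valid hourly data", call. = FALSE)
  stats <- valid |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      mean = mean(.data$pm25_ugm3),
      max = max(.data$pm25_ugm3),
      p95 = quantile(.data$pm25_ugm3, 0.95, names = FALSE),
      p25 = quantile(.data$pm25_ugm3, 0.25, names = FALSE),
      median = median(.data$pm25_ugm3),
      .groups = "drop"
    )
  days <- daily_means(hourly, min_hours) |>
    dplyr::filter(.data$recorded) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      pct_days_exceeding = 100 * mean(.data$daily_mean > guidelines$daily_limit),
      .groups = "drop"
    )
  stats |>
    dplyr::left_join(days, by = "site") |>
    dplyr::mutate(
      n_days = dplyr::coalesce(.data$n_days, 0L),
      pct_days_exceeding = dplyr::coalesce(.data$pct_days_exceeding, NA_real_),
      annual_mean_exceeds = .data$mean > guidelines$annual_limit
    )
}

#' Diurnal, weekly and monthly time-variation profiles
#'
#' Mean of valid hourly values grouped by hour of day (0-23), day of week
#' (Mon-Sun) and calendar month (1-12), per site, with group sizes. Groups
#' with no data are absent rather than zero.
#'
#' @param hourly Validated hourly tibble.
#'
#' @return A list of class `time_variation` with tibbles `diurnal` (`site`,
#'   `hour`, `mean`, `n`), `weekly` (`site`, `wday`, `mean`, `n`) and
#'   `monthly` (`site`, `month`, `mean`, `n`).
#' @export
time_variation <- function(hourly) {
  valid <- dplyr::filter(hourly, .data$status == "valid")
  if (!nrow(valid)) stop("no valid hourly data", call. = FALSE)
  profile <- function(df, key) {
    df |>
      dplyr::group_by(.data$site, .data[[key]]) |>
      dplyr::summarise(mean = mean(.data$pm25_ugm3), n = dplyr::n(),
                       .groups = "drop")
  }
  keyed <- valid |>
    dplyr::mutate(
      hour = lubridate::hour(.data$hour_start),
      wday = lubridate::wday(.data$hour_start, label = TRUE, abbr = TRUE,
                             week_start = 1, locale = "C"),
      month = lubridate::month(.data$hour_start)
    )
  structure(list(
    diurnal = profile(keyed, "hour"),
    weekly = profile(keyed, "wday"),
    monthly = profile(keyed, "month")
  ), class = "time_variation")
}

#' @export
print.time_variation <- function(x, ...) {
  cat("Time-variation profiles (valid hours only)\n")
  cat("diurnal:\n"); print(x$diurnal, n = 5)
  cat("weekly:\n"); print(x$weekly, n = 5)
  cat("monthly:\n"); print(x$monthly, n = 5)
  invisible(x)
}

#' Pairwise inter-site Pearson correlation of daily means
#'
#' Computed on the intersection of recorded days for each site pair; pairs
#' with fewer than `min_common_days` common days get `NA`. High values
#' (0.95-0.98 in dense urban networks) indicate concentrations dominated by
#' shared regional particulate events.
#'
#' @param daily Tibble from [daily_means()]; only `recorded` days are used.
#' @param min_common_days Minimum common days for a correlation (default 3).
#' @param method Correlation method, default `"pearson"`.
#'
#' @return A long tibble (`site_a`, `site_b`, `n_days`, `r`) covering every
#'   ordered pair including the unit diagonal; `tidyr::pivot_wider()` turns
#'   it into a matrix layout.
#' @export
site_correlation <- function(daily, min_common_days = 3, method = "pearson") {
  rec <- dplyr::filter(daily, .data$recorded)
  sites <- sort(unique(rec$site))
  if (length(sites) < 2) stop("need >= 2 sites with recorded days", call. = FALSE)
  wide <- rec |>
    dplyr::select("site", "date", "daily_mean") |>
    tidyr::pivot_wider(names_from = "site", values_from = "daily_mean")
  tidyr::expand_grid(site_a = sites, site_b = sites) |>
    dplyr::mutate(purrr::map2_dfr(.data$site_a, .data$site_b, function(a, b) {
      ok <- stats::complete.cases(wide[[a]], wide[[b]])
      n <- sum(ok)
      r <- if (a == b) 1 else if (n >= min_common_days) {
        stats::cor(wide[[a]][ok], wide[[b]][ok], method = method)
      } else NA_real_
      tibble::tibble(n_days = n, r = r)
    }))
}
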