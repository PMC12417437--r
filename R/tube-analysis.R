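#' Assign a tube deployment to the calendar month it best represents
#'
#' A four-week deployment rarely sits wholly inside one calendar month; each
#' deployment is assigned to the month containing the largest number of its
#' exposure days (inclusive calendar dates from deployment to collection),
#' ties broken toward the earlier month.
#'
#' @param deploy_start,deploy_end Deployment and collection datetimes
#'   (vectorised; POSIXct, Date or ISO 8601 strings).
#'
#' @return A Date vector of first-of-month dates.
#' @export
#'
#' @examples
#' assign_month("2021-04-03", "2021-05-01") # April: 28 vs 1 exposure days
#' assign_month("2021-04-17", "2021-05-15") # May: 14 vs 15 exposure days
assign_month <- function(deploy_start, deploy_end) {
  deploy_start <- as_utc(deploy_start)
  deploy_end <- as_utc(deploy_end)
  if (any(deploy_end <= deploy_start)) {
    stop("deploy_end must be after deploy_start", call. = FALSE)
  }
  purrr::map2_vec(lubridate::as_date(deploy_start), lubridate::as_date(deploy_end),
                  function(d0, d1) {
    days <- seq(d0, d1, by = "day")
    months <- lubridate::floor_date(days, "month")
    tab <- table(months)
    # ties.method gives the first (earliest) month on ties
    as.Date(names(tab)[which.max(tab)])
  })
}

#' Summary statistics for one triplicate deployment
#'
#' @param values Lab-reported NO2 concentrations (ug/m3), all > 0; nominally
#'   three per deployment.
#' @param cv_threshold Coefficient-of-variation threshold above which the
#'   deployment is flagged for poor precision (default 0.20, mirroring the
#'   +/-20 percent uncertainty usually quoted for diffusion tubes).
#'
#' @return A one-row tibble: `mean_no2`, `n_tubes`, `cv` (sample SD / mean)
#'   and `precision_flag` (`TRUE` iff `cv > cv_threshold` or fewer than two
#'   tubes).
#' @export
#'
#' @examples
#' triplicate_stats(c(10, 12, 14))
triplicate_stats <- function(values, cv_threshold = 0.20) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("tube values must be finite and > 0", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  cv <- if (n >= 2) sd(values) / m else NA_real_
  tibble::tibble(
    mean_no2 = m, n_tubes = n, cv = cv,
    precision_flag = n < 2 | (!is.na(cv) & cv > cv_threshold)
  )
}

#' Monthly tube results from deployment records
#'
#' Groups individual tube records into deployments (one per location and
#' deployment start, plus any extra grouping columns present such as
#' `period`), assigns each to its best-represented calendar month and
#' computes triplicate statistics.
#'
#' @param deployments Tibble with columns `location`, `deploy_start`,
#'   `deploy_end`, `no2_ugm3`, and optionally `period` and `tube_id`.
#' @param cv_threshold Passed to [triplicate_stats()].
#'
#' @return A tibble with one row per deployment: `location` (and `period` if
#'   present), `month`, `mean_no2`, `n_tubes`, `cv`, `precision_flag`.
#' @export
monthly_tube_results <- function(deployments, cv_threshold = 0.20) {
  stopifnot_columns(deployments, c("location", "deploy_start", "deploy_end", "no2_ugm3"),
                    "deployments")
  dur_weeks <- as.numeric(difftime(deployments$deploy_end, deployments$deploy_start,
                                   units = "weeks"))
  if (any(dur_weeks < 2 | dur_weeks > 6)) {
    warning("deployment duration outside the nominal 2-6 week range", call. = FALSE)
  }
  keys <- intersect(c("location", "period", "deploy_start", "deploy_end"),
                    names(deployments))
  deployments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(triplicate_stats(.data$no2_ugm3, cv_threshold),
                     .groups = "drop") |>
    dplyr::mutate(month = assign_month(.data$deploy_start, .data$deploy_end)) |>
    dplyr::select(dplyr::all_of(setdiff(keys, c("deploy_start", "deploy_end"))),
                  "month", "mean_no2", "n_tubes", "cv", "precision_flag")
}

#' Percent accuracy of tube means against a reference monitor
#'
#' `100 * (tube_mean - reference_mean) / reference_mean`: the signed relative
#' difference of the tube estimate from a co-located (or nearby
#' urban-background) reference monitor's mean for the same period.
#'
#' @param tube_mean Tube-derived mean NO2, ug/m3 (vectorised).
#' @param reference_mean Reference monitor mean NO2, ug/m3, > 0.
#'
#' @return Percent accuracy (positive = tube reads high).
#' @export
#'
#' @examples
#' percent_accuracy(18.3, 20.4)
percent_accuracy <- function(tube_mean, reference_mean) {
  if (any(!is.finite(reference_mean)) || any(reference_mean <= 0)) {
    stop("reference_mean must be finite and > 0", call. = FALSE)
  }
  100 * (tube_mean - reference_mean) / reference_mean
}

#' Accuracy table of monthly tube results against reference monthly means
#'
#' @param monthly Tibble from [monthly_tube_results()] (one location's
#'   co-location results, or filtered to one).
#' @param reference Tibble of reference monthly means (`month` Date,
#'   `no2_ugm3`).
#'
#' @return `monthly` joined to the reference with a `pct_accuracy` column;
#'   months absent from the reference are dropped.
#' @export
accuracy_table <- function(monthly, reference) {
  stopifnot_columns(reference, c("month", "no2_ugm3"), "reference")
  monthly |>
    dplyr::inner_join(dplyr::rename(reference, reference_no2 = "no2_ugm3"),
                      by = "month") |>
    dplyr::mutate(pct_accuracy = percent_accuracy(.data$mean_no2, .data$reference_no2))
}

#' Per-location mean over a sampling period
#'
#' Arithmetic mean of monthly tube means per location over a requested set of
#' months (e.g. a 4-month sampling period); locations missing some requested
#' months are averaged over the months available, with the number used
#' reported.
#'
#' @param monthly Tibble from [monthly_tube_results()].
#' @param months Date vector of first-of-month dates to include; `NULL` means
#'   all months present.
#'
#' @return A tibble per location (and `period` if present): `mean_no2`,
#'   `n_months`.
#' @export
period_summary <- function(monthly, months = NULL) {
  sel <- if (is.null(months)) monthly else
    dplyr::filter(monthly, .data$month %in% as.Date(months))
  if (!nrow(sel)) stop("no monthly results in the requested months", call. = FALSE)
  keys <- intersect(c("location", "period"), names(sel))
  sel |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_no2 = mean(.data$mean_no2),
                     n_months = dplyr::n(), .groups = "drop")
}
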