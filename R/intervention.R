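#' Month-match baseline and follow-up tube results
#'
#' An intervention comparison is only meaningful on months observed in both
#' periods (similar meteorological seasons); this returns, per location, the
#' calendar months (1-12) present in both the baseline and follow-up monthly
#' results. Unmatched months are reported and excluded; locations with no
#' common month are skipped with a warning.
#'
#' @param baseline,followup Tibbles from [monthly_tube_results()].
#'
#' @return A tibble (`location`, `month_of_year`) of matched months, with the
#'   unmatched (location, period, month) combinations in attribute
#'   `unmatched`.
#' @export
month_match <- function(baseline, followup) {
  if (!nrow(baseline) || !nrow(followup)) {
    stop("both periods must be non-empty", call. = FALSE)
  }
  moy <- function(df, period) {
    df |>
      dplyr::transmute(location = .data$location, period = period,
                       month_of_year = lubridate::month(.data$month)) |>
      dplyr::distinct()
  }
  b <- moy(baseline, "baseline")
  f <- moy(followup, "followup")
  matched <- dplyr::inner_join(b, dplyr::select(f, -"period"),
                               by = c("location", "month_of_year")) |>
    dplyr::select("location", "month_of_year") |>
    dplyr::arrange(.data$location, .data$month_of_year)
  unmatched <- dplyr::bind_rows(
    dplyr::anti_join(b, matched, by = c("location", "month_of_year")),
    dplyr::anti_join(f, matched, by = c("location", "month_of_year"))
  )
  skipped <- setdiff(union(b$location, f$location), matched$location)
  if (length(skipped)) {
    warning("no matched months for location(s): ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  attr(matched, "unmatched") <- unmatched
  matched
}

#' Welch's two-sample comparison of baseline vs follow-up
#'
#' Welch's unequal-variance t-test of baseline minus follow-up, with the
#' Welch-Satterthwaite degrees of freedom, a two-sided p-value and a
#' `(1 - alpha)` confidence interval for the difference. The pooled-variance
#' Student's test is available via `var_equal = TRUE`. The degenerate case of
#' zero variance in both groups with equal means returns `t = 0`, `p = 1`.
#'
#' @param baseline,followup Numeric vectors (monthly means), each of length
#'   >= 2.
#' @param alpha Significance level (default 0.05; the interval is the
#'   `100 * (1 - alpha)` percent CI).
#' @param var_equal Use the pooled-variance Student's t-test instead of
#'   Welch's.
#' @param location Optional location label carried into the result.
#'
#' @return An object of class `welch_intervention` with [tidy()] and
#'   [glance()] methods; fields include `baseline_mean`, `followup_mean`,
#'   `difference` (baseline - follow-up), `t_stat`, `df`, `p_value`,
#'   `ci_low`, `ci_high` and `significant`.
#' @export
#'
#' @examples
#' tidy(welch_compare(c(30, 31, 32), c(22, 23, 24)))
welch_compare <- function(baseline, followup, alpha = 0.05, var_equal = FALSE,
                          location = NA_character_) {
  if (length(baseline) < 2 || length(followup) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  m1 <- mean(baseline); m2 <- mean(followup)
  if (sd(baseline) == 0 && sd(followup) == 0) {
    if (m1 != m2) {
      stop("zero variance in both groups with unequal means: t is undefined",
           call. = FALSE)
    }
    res <- list(t_stat = 0, df = length(baseline) + length(followup) - 2,
                p_value = 1, ci = c(0, 0))
  } else {
    ht <- t.test(baseline, followup, var.equal = var_equal,
                 conf.level = 1 - alpha)
    res <- list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value, ci = unname(ht$conf.int))
  }
  structure(list(
    location = location,
    n_baseline = length(baseline), n_followup = length(followup),
    baseline_mean = m1, followup_mean = m2, difference = m1 - m2,
    t_stat = res$t_stat, df = res$df, p_value = res$p_value,
    ci_low = res$ci[1], ci_high = res$ci[2],
    alpha = alpha, significant = res$p_value < alpha,
    method = if (var_equal) "Student" else "Welch"
  ), class = "welch_intervention")
}

#' @export
print.welch_intervention <- function(x, ...) {
  cat(sprintf("%s two-sample comparison%s\n", x$method,
              if (is.na(x$location)) "" else paste0(" at ", x$location)))
  cat(sprintf("  baseline %.2f (n=%d) vs follow-up %.2f (n=%d)\n",
              x$baseline_mean, x$n_baseline, x$followup_mean, x$n_followup))
  cat(sprintf("  difference %.2f [%.2f, %.2f], t=%.3f, df=%.2f, p=%.4g%s\n",
              x$difference, x$ci_low, x$ci_high, x$t_stat, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @rdname welch_compare
#' @param x A `welch_intervention` object.
#' @param ... Unused.
#' @method tidy welch_intervention
#' @export
tidy.welch_intervention <- function(x, ...) {
  tibble::tibble(
    location = x$location,
    n_baseline = x$n_baseline, n_followup = x$n_followup,
    baseline_mean = x$baseline_mean, followup_mean = x$followup_mean,
    difference = x$difference, t_stat = x$t_stat, df = x$df,
    p_value = x$p_value, ci_low = x$ci_low, ci_high = x$ci_high,
    significant = x$significant
  )
}

#' @rdname welch_compare
#' @method glance welch_intervention
#' @export
glance.welch_intervention <- function(x, ...) tidy(x, ...)

#' Month-matched intervention comparison across locations
#'
#' For every location, matches calendar months between the baseline and
#' follow-up monthly tube results, then compares the matched monthly means
#' with [welch_compare()]. Locations with fewer than two matched months are
#' skipped with a warning. No multiple-testing correction is applied by
#' default (per-location tests); set `p_adjust` to a [stats::p.adjust()]
#' method (e.g. `"bonferroni"`) to correct.
#'
#' @param baseline,followup Tibbles from [monthly_tube_results()].
#' @param alpha Significance level.
#' @param var_equal Use pooled-variance Student's t instead of Welch.
#' @param p_adjust Multiple-testing correction method (default `"none"`).
#'
#' @return A tibble with one row per compared location: matched months,
#'   group means, difference (baseline - follow-up), Welch statistic, df,
#'   p-value, CI and significance at `alpha`.
#' @export
compare_locations <- function(baseline, followup, alpha = 0.05,
                              var_equal = FALSE, p_adjust = "none") {
  matched <- month_match(baseline, followup)
  pick <- function(df, loc, months) {
    df |>
      dplyr::filter(.data$location == loc,
                    lubridate::month(.data$month) %in% months) |>
      dplyr::pull(.data$mean_no2)
  }
  out <- matched |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(months_used = list(.data$month_of_year), .groups = "drop") |>
    dplyr::mutate(n_months = lengths(.data$months_used))
  rows <- purrr::pmap(out, function(location, months_used, n_months) {
    if (n_months < 2) {
      warning("location '", location, "' has fewer than 2 matched months; skipped",
              call. = FALSE)
      return(NULL)
    }
    b <- pick(baseline, location, months_used)
    f <- pick(followup, location, months_used)
    res <- tidy(welch_compare(b, f, alpha = alpha, var_equal = var_equal,
                              location = location))
    res$months_used <- paste(months_used, collapse = ",")
    res$n_months <- n_months
    res
  })
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) stop("no location had >= 2 matched months", call. = FALSE)
  res |>
    dplyr::mutate(p_value = p.adjust(.data$p_value, method = p_adjust),
                  significant = .data$p_value < alpha) |>
    dplyr::select("location", "n_months", "months_used", dplyr::everything())
}

#' Screen locations for significant baseline/follow-up differences
#'
#' @param results Tibble from [compare_locations()].
#' @param alpha Significance level (default 0.05).
#'
#' @return The significant rows of `results`, sorted by difference
#'   descending.
#' @export
location_screen <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("results must be non-empty", call. = FALSE)
  results |>
    dplyr::filter(.data$p_value < alpha) |>
    dplyr::arrange(dplyr::desc(.data$difference))
}
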