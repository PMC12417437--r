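#' Plot daily mean concentrations against the 24-h guideline
#'
#' Line plot of daily means per site with the 24-h guideline as a dashed
#' reference line; days below the validity threshold are omitted.
#'
#' @param daily Tibble from [daily_means()].
#' @param guidelines A [guideline_set()] supplying the dashed 24-h limit.
#'
#' @return A ggplot object.
#' @export
plot_daily_series <- function(daily, guidelines = guideline_set()) {
  rec <- dplyr::filter(daily, .data$recorded)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$date, y = .data$daily_mean,
                                    colour = .data$site)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = guidelines$daily_limit,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = expression(paste("daily mean (", mu, "g ", m^-3, ")")),
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' @describeIn time_variation Plot the diurnal, weekly and monthly profiles
#'   as faceted panels, one line per site.
#' @param object A `time_variation` object.
#' @param ... Unused.
#' @method autoplot time_variation
#' @export
autoplot.time_variation <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::mutate(object$diurnal, profile = "diurnal (hour)",
                  key = factor(.data$hour, levels = 0:23)),
    dplyr::mutate(object$weekly, profile = "weekly (day)",
                  key = factor(as.character(.data$wday),
                               levels = levels(object$weekly$wday))),
    dplyr::mutate(object$monthly, profile = "monthly",
                  key = factor(.data$month, levels = 1:12))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$key, y = .data$mean,
                                     colour = .data$site,
                                     group = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~profile, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(paste("mean (", mu, "g ", m^-3, ")")),
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' @describeIn run_qc_pipeline Plot hour counts per validation status and
#'   site.
#' @param object A `qc_run` object.
#' @method autoplot qc_run
#' @export
autoplot.qc_run <- function(object, ...) {
  counts <- tidy(object) |>
    dplyr::mutate(status = factor(.data$status, levels = qc_statuses))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$site, y = .data$hours,
                                       fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "hours", fill = "status") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
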