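# Internal helpers shared across modules.

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(format(x), tz = "UTC"))
  }
  out <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", truncated = 3))
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp(s): ", paste(head(x[is.na(out)], 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Number of whole clock hours in [start, end).
n_clock_hours <- function(period_start, period_end) {
  period_start <- as_utc(period_start)
  period_end <- as_utc(period_end)
  if (period_end <= period_start) {
    stop("period_end must be after period_start", call. = FALSE)
  }
  as.integer(floor(as.numeric(difftime(period_end, period_start, units = "hours"))))
}

stopifnot_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
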