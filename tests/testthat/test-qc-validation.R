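raw_tbl <- function(ts, x, site = "a") {
  tibble::tibble(timestamp = as.POSIXct(ts, tz = "UTC"), site = site,
                 pm25_ugm3 = as.numeric(x))
}

test_that("hourly aggregation averages available readings and applies the hour rule", {
  t0 <- as.POSIXct("2021-06-01 10:00:00", tz = "UTC")
  raw <- raw_tbl(c(t0 + c(0, 900, 1800, 2700),        # 4 readings
                   t0 + 3600 + c(0, 900),             # 2 readings
                   t0 + 7200 + c(0, 900, 1800)),      # exactly 3 readings
                 c(2, 4, 6, 8, 1, 1, 3, 3, 3))
  h <- aggregate_to_hourly(raw)
  expect_equal(h$pm25_ugm3, c(5, 1, 3))
  expect_equal(h$n_readings, c(4L, 2L, 3L))
  expect_equal(h$status, c("valid", "removed_step1_hour", "valid"))
})

test_that("unsorted or duplicated raw timestamps are an input error", {
  t0 <- as.POSIXct("2021-06-01 10:00:00", tz = "UTC")
  expect_error(aggregate_to_hourly(raw_tbl(c(t0 + 900, t0), c(1, 2))),
               "strictly increasing")
  expect_error(aggregate_to_hourly(raw_tbl(c(t0, t0), c(1, 2))),
               "strictly increasing")
  expect_error(aggregate_to_hourly(raw_tbl(t0, -1)), ">= 0")
})

# Hourly fixture: `hours_per_day[d]` valid hours on day d of June 2021.
june_hours <- function(hours_per_day, site = "a") {
  rows <- purrr::imap_dfr(hours_per_day, function(nh, d) {
    if (nh == 0) return(NULL)
    start <- sprintf("2021-06-%02d", d)
    hourly_tbl(10 + seq_len(nh) / 10, start = start, site = site)
  })
  rows
}

test_that("day and month coverage boundaries are inclusive at 18 h and 23 days", {
  # 23 days of 18 h: everything survives
  ok <- apply_completeness(june_hours(rep(c(18, 0), c(23, 7))))
  expect_true(all(ok$status == "valid"))
  # a 17 h day fails the day rule (and drops the month to 22 covered days)
  h <- june_hours(rep(c(18, 17, 0), c(22, 1, 7)))
  out <- apply_completeness(h)
  day17 <- lubridate::as_date(out$hour_start) == as.Date("2021-06-23")
  expect_true(all(out$status[day17] == "removed_step1_day"))
  expect_true(all(out$status[!day17] == "removed_step1_month"))
})

test_that("the month rule removes whole uncovered months", {
  out <- apply_completeness(june_hours(rep(c(18, 0), c(22, 8))))
  expect_true(all(out$status == "removed_step1_month"))
  expect_false(any(out$status == "valid"))
})

test_that("the meteorology mask keeps in-envelope and unjoined hours", {
  h <- hourly_tbl(c(5, 6, 7, 8), start = "2021-06-01")
  met <- tibble::tibble(
    timestamp = h$hour_start[1:3],
    temp_c = c(40, 20, 20),
    rh_pct = c(50, 50, 30)
  )
  out <- apply_met_filter(h, met)
  expect_equal(out$status, c("removed_step2",  # t = 40 out of (-10, 35)
                             "valid",          # 20 C, 50% inside
                             "removed_step2",  # RH 30 fails literal keep RH > 35
                             "valid"))         # no met record: retained
  # the high-RH bound is configurable
  cfg <- validation_config(rh_min = 0, rh_max = 85)
  met2 <- tibble::tibble(timestamp = h$hour_start[1:3],
                         temp_c = 20, rh_pct = c(90, 50, 30))
  expect_equal(apply_met_filter(h, met2, cfg)$status,
               c("removed_step2", "valid", "valid", "valid"))
})

test_that("static filter flags all members of zero-SD windows", {
  five <- hourly_tbl(c(1, rep(4, 5), 2))
  expect_equal(apply_static_filter(five)$status,
               c("valid", rep("removed_step3", 5), "valid"))
  # one differing value breaks the window
  broken <- hourly_tbl(c(4, 4, 5, 4, 4))
  expect_true(all(apply_static_filter(broken)$status == "valid"))
  # a 7-sample stuck run is fully removed (overlapping windows)
  seven <- hourly_tbl(c(1, 2, rep(5, 7), 3, 4))
  expect_equal(sum(apply_static_filter(seven)$status == "removed_step3"), 7)
})

test_that("static filter runs over valid samples in time order, ignoring gaps", {
  h <- hourly_tbl(c(3, 3, 9, 3, 3, 3), status = "valid")
  h$status[3] <- "removed_step2"  # the 9 is already gone: 5 remaining 3s are stuck
  out <- apply_static_filter(h)
  expect_equal(out$status,
               c(rep("removed_step3", 2), "removed_step2", rep("removed_step3", 3)))
})

test_that("MAD filter reproduces the worked monthly examples", {
  out <- apply_mad_filter(hourly_tbl(c(3, 3, 4, 5, 5, 6, 30)))
  expect_equal(out$status, c(rep("valid", 6), "removed_step4"))
  # constant month: MAD = 0, nothing removed
  expect_true(all(apply_mad_filter(hourly_tbl(rep(7, 30)))$status == "valid"))
  # symmetric month inside the bounds
  expect_true(all(apply_mad_filter(hourly_tbl(c(4, 5, 6)))$status == "valid"))
})

test_that("MAD filter is applied per site and calendar month", {
  spread <- c(rep(c(4, 5, 6), 7), 50)  # median 5, MAD 1.4826: only 50 is out
  h <- dplyr::bind_rows(
    hourly_tbl(spread, start = "2021-06-01", site = "a"),
    hourly_tbl(rep(50, 22), start = "2021-06-01", site = "b"),
    hourly_tbl(spread, start = "2021-07-01", site = "a")
  )
  out <- apply_mad_filter(h)
  expect_equal(sum(out$status == "removed_step4"), 2)
  expect_true(all(out$status[out$site == "a" & out$pm25_ugm3 == 50] == "removed_step4"))
  expect_true(all(out$status[out$site == "b"] == "valid"))
})

test_that("filters change only status, never hourly values, and removal is monotone", {
  cfg <- network_config(n_sites = 1, period_end = "2021-10-01",
                        noise_sd = 2, episodic_sd = 4, seed = 21)
  net <- generate_network(cfg)
  met <- generate_meteorology(period_end = "2021-10-01", mean_temp = 20,
                              temp_seasonal_amplitude = 14, seed = 21)
  h0 <- aggregate_to_hourly(net$series)
  h1 <- apply_completeness(h0)
  h2 <- apply_met_filter(h1, met)
  h3 <- apply_static_filter(h2)
  h4 <- apply_mad_filter(h3)
  for (h in list(h1, h2, h3, h4)) {
    expect_equal(dplyr::arrange(h[c("site", "hour_start", "pm25_ugm3", "n_readings")],
                                site, hour_start),
                 dplyr::arrange(h0[c("site", "hour_start", "pm25_ugm3", "n_readings")],
                                site, hour_start))
  }
  valid_counts <- vapply(list(h0, h1, h2, h3, h4),
                         function(h) sum(h$status == "valid"), integer(1))
  expect_true(all(diff(valid_counts) <= 0))
})

test_that("capture report partitions every potential hour", {
  cfg <- network_config(n_sites = 2, period_end = "2021-12-01",
                        noise_sd = 2, episodic_sd = 4, seed = 31)
  net <- generate_network(cfg)
  faults <- fault_spec(gaps = tibble::tibble(
    site = "site_01", start = as.POSIXct("2021-09-10", tz = "UTC"),
    duration_hours = 36))
  faulted <- inject_faults(net$series, faults)
  qc <- run_qc_pipeline(faulted$series, met = NULL,
                        period_start = "2021-09-01", period_end = "2021-12-01")
  rep <- qc$report
  removed <- rowSums(rep[grep("^removed_", names(rep))])
  expect_true(all(rep$valid_hours + removed + rep$missing_hours == rep$potential_hours))
  expect_true(all(rep$capture_pct >= 0 & rep$capture_pct <= 100))
})

test_that("capture percentages match direct hour counting", {
  # a fully missing 31-day month in a 365-day year
  h <- hourly_tbl(rep(c(5, 6, 7, 8), length.out = 8760), start = "2021-09-01")
  h <- h[lubridate::month(h$hour_start) != 12, ]  # drop December entirely
  rep <- capture_report(h, "2021-09-01", "2022-09-01")
  expect_equal(rep$potential_hours, 8760)
  expect_equal(rep$capture_pct, 100 * (8760 - 744) / 8760, tolerance = 1e-2)
  # Table-style rounding at presentation: 8,059 of 8,760 valid reads as 92.0
  h2 <- hourly_tbl(rep(c(5, 6, 7, 8), length.out = 8059), start = "2021-09-01")
  rep2 <- capture_report(h2, "2021-09-01", "2022-09-01")
  expect_equal(round(rep2$capture_pct, 1), 92.0)
  expect_error(capture_report(h2, "2021-09-01", "2021-09-01"), "period_end")
})

test_that("the full pipeline applies steps once, in order", {
  cfg <- clean_year_config(n_sites = 1, seed = 2)
  net <- generate_network(cfg)
  t0 <- as.POSIXct("2021-10-05 08:00:00", tz = "UTC")
  faults <- fault_spec(
    statics = tibble::tibble(site = "site_01", start = t0, duration_hours = 6,
                             held_value = 7),
    spikes = tibble::tibble(site = "site_01", timestamp = t0 + 5 * 86400,
                            magnitude = 60)
  )
  faulted <- inject_faults(net$series, faults)
  qc <- run_qc_pipeline(faulted$series, met = benign_met(seed = 2),
                        period_start = cfg$period_start,
                        period_end = cfg$period_end)
  h <- qc$hourly
  static_hours <- h$hour_start >= t0 & h$hour_start < t0 + 6 * 3600
  expect_true(all(h$status[static_hours] == "removed_step3"))
  spike_hour <- h$hour_start == lubridate::floor_date(t0 + 5 * 86400, "hour")
  expect_equal(h$status[spike_hour], "removed_step4")
  # statuses are mutually exclusive: one status per hour record
  expect_equal(anyDuplicated(h[c("site", "hour_start")]), 0L)
})
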