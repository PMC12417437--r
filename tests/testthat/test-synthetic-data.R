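test_that("network generation is a pure function of its config", {
  cfg <- network_config(n_sites = 2, period_end = "2021-09-08", seed = 42)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  # and changing the seed changes the output
  c <- generate_network(network_config(n_sites = 2, period_end = "2021-09-08",
                                       seed = 43))
  expect_false(identical(a$series$pm25_ugm3, c$series$pm25_ugm3))
})

test_that("degenerate config collapses to the regional mean", {
  cfg <- network_config(n_sites = 3, period_end = "2021-09-03",
                        regional_mean = 7, site_offsets = 0,
                        diurnal_amplitude = 0, weekly_amplitude = 0,
                        noise_sd = 0, episodic_sd = 0, seed = 1)
  net <- generate_network(cfg)
  expect_true(all(net$series$pm25_ugm3 == 7))
  # every site has a reading at every cadence tick
  expect_equal(nrow(net$series), 3 * 2 * 24 * 4)
})

test_that("generated concentrations are non-negative and grid-complete", {
  cfg <- network_config(n_sites = 2, period_end = "2021-09-15",
                        regional_mean = 3, noise_sd = 4, seed = 9)
  net <- generate_network(cfg)
  expect_true(all(net$series$pm25_ugm3 >= 0))
  expect_true(all(net$truth$truth_ugm3 >= 0))
  counts <- dplyr::count(net$series, site)
  expect_true(all(counts$n == 14 * 96))
})

test_that("a fully regional network has near-unit daily correlations", {
  cfg <- network_config(n_sites = 4, period_end = "2021-12-01",
                        regional_weight = 1, seed = 11)
  net <- generate_network(cfg)
  hourly <- aggregate_to_hourly(net$series)
  daily <- daily_means(hourly)
  cors <- site_correlation(daily)
  off_diag <- dplyr::filter(cors, site_a != site_b)
  expect_true(all(off_diag$r > 0.99))
})

test_that("network config invariants are enforced", {
  expect_error(network_config(n_sites = 0), "n_sites")
  expect_error(network_config(period_start = "2022-01-01",
                              period_end = "2021-01-01"), "period_end")
  expect_error(network_config(regional_weight = 1.2), "regional_weight")
  expect_error(network_config(noise_sd = -1), "SD")
})

test_that("meteorology is seeded, bounded and hits its configured mean", {
  met1 <- generate_meteorology(period_end = "2021-10-01", seed = 4)
  met2 <- generate_meteorology(period_end = "2021-10-01", seed = 4)
  expect_identical(met1, met2)
  expect_true(all(met1$rh_pct >= 0 & met1$rh_pct <= 100))

  year <- generate_meteorology("2021-09-01", "2022-09-01", mean_temp = 10, seed = 2)
  expect_equal(nrow(year), 8760)
  expect_lt(abs(mean(year$temp_c) - 10), 0.5)
})

test_that("fault injection alters exactly the ticks in its mask", {
  cfg <- network_config(n_sites = 1, period_end = "2021-09-08", seed = 3)
  net <- generate_network(cfg)

  # empty spec is the identity
  empty <- inject_faults(net$series, fault_spec())
  expect_identical(empty$series, net$series)
  expect_equal(nrow(empty$mask), 0)

  t0 <- as.POSIXct("2021-09-02 06:00:00", tz = "UTC")
  faults <- fault_spec(
    gaps = tibble::tibble(site = "site_01", start = t0 + 86400,
                          duration_hours = 2),
    statics = tibble::tibble(site = "site_01", start = t0,
                             duration_hours = 6, held_value = 12.5),
    spikes = tibble::tibble(site = "site_01",
                            timestamp = t0 + 3 * 86400, magnitude = 50)
  )
  out <- inject_faults(net$series, faults)
  # one 6 h static run holds one value over exactly 24 consecutive 15-min ticks
  held <- dplyr::filter(out$series, timestamp >= t0, timestamp < t0 + 6 * 3600)
  expect_equal(nrow(held), 24)
  expect_true(all(held$pm25_ugm3 == 12.5))
  # gap run deletes its ticks
  expect_equal(nrow(out$series), nrow(net$series) - 8)
  # spike adds its magnitude at one tick
  before <- net$series$pm25_ugm3[net$series$timestamp == t0 + 3 * 86400]
  after <- out$series$pm25_ugm3[out$series$timestamp == t0 + 3 * 86400]
  expect_equal(after, before + 50)
  # mask cardinality equals the sum of injected tick counts
  expect_equal(nrow(out$mask), 8 + 24 + 1)
  expect_equal(as.vector(table(out$mask$fault)[c("gap", "static", "spike")]),
               c(8, 24, 1))
})

test_that("overlapping faults on the same tick are rejected", {
  cfg <- network_config(n_sites = 1, period_end = "2021-09-08", seed = 3)
  net <- generate_network(cfg)
  t0 <- as.POSIXct("2021-09-02 06:00:00", tz = "UTC")
  faults <- fault_spec(
    gaps = tibble::tibble(site = "site_01", start = t0, duration_hours = 2),
    statics = tibble::tibble(site = "site_01", start = t0 + 3600,
                             duration_hours = 2, held_value = 5)
  )
  expect_error(inject_faults(net$series, faults), "ambiguous")
  outside <- fault_spec(gaps = tibble::tibble(
    site = "site_01", start = as.POSIXct("2022-01-01", tz = "UTC"),
    duration_hours = 2))
  expect_error(inject_faults(net$series, outside), "span")
})

test_that("tube study generation honours its noise and intervention settings", {
  base <- tube_study_config(locations = c("a", "b"),
                            location_truth = c(a = 20, b = 30),
                            intervention_site = "b", intervention_delta = 0,
                            tube_noise_rel_sd = 0, seed = 6)
  study <- generate_tube_study(base)
  joined <- dplyr::left_join(study$deployments,
                             dplyr::mutate(study$truth, month = as.Date(month)),
                             by = c("location", "period"),
                             relationship = "many-to-many") |>
    dplyr::filter(as.Date(deploy_start) == month)
  # zero noise: every reported value equals its latent truth
  expect_true(all(joined$no2_ugm3 == joined$truth_no2))
  # zero delta: baseline and follow-up truths identical per location
  truths <- tidyr::pivot_wider(dplyr::distinct(study$truth, location, period, truth_no2),
                               names_from = period, values_from = truth_no2)
  expect_equal(truths$baseline, truths$followup)

  withdelta <- generate_tube_study(tube_study_config(
    locations = c("a", "b"), location_truth = c(a = 20, b = 30),
    intervention_site = "b", intervention_delta = 8,
    tube_noise_rel_sd = 0, seed = 6))
  t2 <- dplyr::distinct(withdelta$truth, location, period, truth_no2) |>
    tidyr::pivot_wider(names_from = period, values_from = truth_no2)
  expect_equal(t2$baseline - t2$followup, c(0, 8))
})

test_that("single-tube relative errors follow the configured noise scale", {
  cfg <- tube_study_config(locations = "a", location_truth = c(a = 20),
                           baseline_months = as.Date("2021-04-01"),
                           followup_months = as.Date("2023-04-01"),
                           intervention_site = NULL, intervention_delta = 0,
                           tube_noise_rel_sd = 0.075, n_tubes = 2000, seed = 8)
  study <- generate_tube_study(cfg)
  rel_err <- study$deployments$no2_ugm3 / 20 - 1
  # ~95.45% of Normal(0, 0.075) draws lie within +/-0.15 (2 SD)
  expect_lt(abs(mean(abs(rel_err) <= 0.15) - 0.9545), 0.02)
  expect_lt(abs(sd(rel_err) - 0.075), 0.005)
})
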