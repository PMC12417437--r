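# Independent brute-force oracles and fixture builders shared across tests.

# Build a valid hourly tibble from a numeric vector, hours consecutive from
# `start`. Keeping the default start inside one calendar month makes the
# vector a single site-month for the MAD filter.
hourly_tbl <- function(x, start = "2021-06-01", site = "a",
                       status = "valid", n_readings = 4L) {
  tibble::tibble(
    site = site,
    hour_start = as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(x) - 1),
    pm25_ugm3 = as.numeric(x),
    n_readings = n_readings,
    status = status
  )
}

# Brute force: enumerate every length-w window; a window with zero standard
# deviation flags all its members.
oracle_static_flags <- function(x, w) {
  n <- length(x)
  flag <- rep(FALSE, n)
  if (n >= w) {
    for (i in seq_len(n - w + 1)) {
      win <- x[i:(i + w - 1)]
      if (sd(win) == 0) flag[i:(i + w - 1)] <- TRUE
    }
  }
  flag
}

# Definitional MAD outlier flags: median, MAD = b * median(|x - median|),
# exclude outside median +/- k * MAD; MAD of 0 removes nothing.
oracle_mad_flags <- function(x, b = 1.4826, k = 3) {
  med <- median(x)
  mad_val <- b * median(abs(x - med))
  if (mad_val == 0) return(rep(FALSE, length(x)))
  x < med - k * mad_val | x > med + k * mad_val
}

# Sort-and-interpolate percentile: h = (n - 1) p + 1 on the order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# A full-year raw series with nothing for the validation pipeline to remove:
# deterministic diurnal structure (so moving SDs are nonzero and the monthly
# spread stays well inside 3 MAD) plus modest measurement noise.
clean_year_config <- function(n_sites = 4, seed = 1L) {
  network_config(
    n_sites = n_sites,
    period_start = "2021-09-01", period_end = "2022-09-01",
    regional_mean = 7, regional_weight = 0.9,
    diurnal_amplitude = 3, weekly_amplitude = 0.5,
    noise_sd = 0.4, episodic_sd = 0, seed = seed
  )
}

# Meteorology that never trips the Step 2 envelope.
benign_met <- function(period_start = "2021-09-01", period_end = "2022-09-01",
                       seed = 1L) {
  generate_meteorology(
    period_start = period_start, period_end = period_end,
    mean_temp = 12, temp_seasonal_amplitude = 5, temp_diurnal_amplitude = 3,
    temp_noise_sd = 1, rh_mean = 70, rh_diurnal_amplitude = 6, rh_noise_sd = 3,
    seed = seed
  )
}
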