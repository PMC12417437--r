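---
title: "Methods: sensor validation, tube workflows and intervention comparison in airqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor validation, tube workflows and intervention comparison in airqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airqa)
```

`airqa` analyses low-cost air-quality campaigns: networks of small-form
optical PM2.5 sensors reporting 15-minute averages, and passive NO2 diffusion
tubes deployed in monthly triplicates. This vignette documents the models and
procedures, the parameters that matter, the synthetic-data generator used for
testing, and the design decisions taken where the methodology is genuinely
open.

## The 4-step validation pipeline

Small-form optical particle counters fail in characteristic ways: they drop
readings, stick at a constant output, spike, and report unreliably outside
their temperature/humidity operating envelope. The pipeline in
`run_qc_pipeline()` addresses each failure mode in a single pass, in a fixed
order, on hourly averages of the 15-minute raw data:

1. **Completeness.** An hourly average is valid only if built from at least
   `min_readings_per_hour` (default 3 of a nominal 4) 15-minute readings; a
   day is covered only if it retains `min_hours_per_day` (default 18) valid
   hours; a month is covered only if it retains `min_days_per_month` (default
   23) covered days. Hours on uncovered days or months are discarded. All
   three thresholds are inclusive ("3 or more", "18 or more", "23 or more").
2. **Meteorology mask.** Hours whose joined meteorology falls outside the
   manufacturer envelope are discarded. The default keep-rule is
   `-10 < t < 35` degrees C and `RH > 35` percent, with strict inequalities.
   The humidity rule deserves comment: masking *low* humidity is unusual for
   optical sensors (hygroscopic particle growth is a *high*-RH problem, and
   common practice is to mask RH above ~85 percent). We implement the low-RH
   keep-rule as the documented manufacturer specification but expose both
   bounds (`rh_min`, `rh_max`) so either convention can be applied.
3. **Static data.** Over each site's valid hours in time order, any window of
   `static_window` (default 5) consecutive samples with zero standard
   deviation — all values identical within 1e-12, a pure float-equality
   guard, not a tunable — marks *every* sample in the window as stuck. Runs
   longer than the window are fully removed by overlapping windows. The
   window slides over valid samples ignoring gaps, the most conservative
   reading of a moving-SD rule on an incomplete series.
4. **MAD outliers.** Per site and calendar month, with monthly median `m` of
   the currently valid values and `MAD = b * median(|x - m|)`, values outside
   `m ± k * MAD` are removed (`k = mad_multiplier`, default 3). The scale
   constant `b = 1.4826` is `1/qnorm(0.75)` rounded to 4 decimals, making MAD
   a consistent estimator of the standard deviation under normality.

Two degenerate cases in Step 4 need explicit policy. First, a constant month
has `MAD = 0`; a literal reading would then remove every value differing from
the median at all, so the filter removes nothing and leaves stuck data to
Step 3, whose job it is. Second, the MAD is sometimes written without the
absolute value; the median of *signed* deviations is approximately zero and
degenerates the filter, so the standard absolute-deviation form is the
default and the signed form is available only as an audit flag
(`mad_signed`).

Steps run once, in the listed order; day/month coverage is *not* re-evaluated
after Steps 2–4 remove further hours, because re-iteration would change what
a capture report counts (a `reiterate_completeness` switch exists for
sensitivity analysis). Statuses are mutually exclusive — the first step that
removes an hour wins — and filters never alter values, only status, so the
capture report is an exact partition: for every site,
`valid + removed-by-step + missing = potential clock hours in the period`
(8,760 for a 365-day year). Hours with no meteorology record are retained in
Step 2: absence of a covariate is not evidence of an envelope violation
(these hours remain identifiable in the log output of the CLI).

## Diffusion-tube workflow

Triplicate tubes are averaged per deployment (`monthly_tube_results()`), and
each four-week deployment is assigned to the calendar month containing the
largest number of its exposure days, counted as inclusive calendar dates;
ties break to the earlier month, a deterministic convention aligned with
deployment-start bookkeeping. Precision is screened by the coefficient of
variation (sample SD over mean; `n - 1` denominator, the small-n convention):
deployments with `cv > 0.20` — mirroring the ±20 percent uncertainty usually
quoted for tubes — or with fewer than two surviving tubes are flagged, not
dropped; the analyst decides. Accuracy against a co-located reference monitor
is the signed relative difference `100 * (tube - reference) / reference`.
Note that published accuracy figures are generally computed from unrounded
laboratory values, so they cannot be reproduced exactly from rounded monthly
concentrations; the operation is defined by the formula, not by any printed
table.

## Exceedance statistics and profiles

`exceedance_summary()` reports mean, max and 95th/25th/median percentiles of
valid hourly values, using linear interpolation between order statistics
(R's default type-7 quantile; the common convention, stated here because
percentile conventions differ). Daily means use calendar days with at least
18 valid hours ("recorded" days), reusing the Step 1 day rule so that the
exceedance denominator matches the completeness semantics. A day exceeds the
24-h guideline only if its mean is strictly greater than the limit —
"exceeded" read literally. WHO (2021) defaults: PM2.5 annual 5 and 24-h 15
ug/m3; NO2 annual 10 and 24-h 25 ug/m3. Inter-site correlations are Pearson
correlations of daily means on the intersection of recorded days (pairs with
fewer than 3 common days are NA); daily averaging is the default because
hourly correlations are dominated by diurnal cycles rather than the regional
events of interest.

## Intervention comparison

Baseline and follow-up campaigns are compared per location on month-matched
monthly means: only calendar months observed in both periods enter, keeping
the comparison within similar meteorological seasons. The test is Welch's
two-sample t (Welch–Satterthwaite df) on the matched monthly means; Welch is
the safer default where only "a t-test" is specified, since it reduces to
Student's under equal variances, and the pooled-variance test remains
available (`var_equal = TRUE`). The unit of analysis is the monthly
triplicate mean (n = matched months per group), not the individual tube —
individual tubes within a deployment share exposure conditions and are not
independent replicates of the month. No multiple-testing correction is
applied by default because screening reports per-location tests, but
`p_adjust = "bonferroni"` (or any `p.adjust` method) is available; with six
locations at alpha = 0.05 roughly one borderline false positive per four
campaigns is expected, as the README example illustrates.

## The synthetic-data generator

Real campaign data from institutional sites is rarely shareable, so every
stage is exercised against `generate_network()`, `generate_meteorology()`,
`inject_faults()` and `generate_tube_study()`, all pure functions of their
seeded configs.

Each site's latent PM2.5 signal is
`w * shared(t) + (1 - w) * local_i(t) + offset_i + diurnal + weekly`, floored
at zero, with iid Gaussian measurement noise added on top. `shared` and
`local_i` are mean-one lognormal transforms of AR(1) Gaussian processes
scaled by `regional_mean` — positive, episodic, autocorrelated series that
reproduce the two salient features of dense urban networks (near-unit
inter-site correlation of daily means when `w` is near 1, and skewed
episodic peaks) without claiming a physical dispersion model. The diurnal
term is a cosine peaking at 08:00 (morning traffic), the weekly term a
Tuesday increment; both are additive so profile recovery can be checked
against known amplitudes. Defaults (`regional_mean = 7`,
`regional_weight = 0.9`, `episodic_sd = 3`, `noise_sd = 1.5`,
`diurnal_amplitude = 2`, `weekly_amplitude = 1` ug/m3) give annual means
near 7 ug/m3 and high inter-site correlations, the regime of a typical urban
background network. The episodic scale and autocorrelation (`episodic_sd`,
`episodic_ar`) are exposed separately from `noise_sd` so that deterministic
degenerate configurations (all stochastic terms off) remain expressible.

Fault injection writes the ground truth down: gap runs delete ticks, static
runs overwrite with a held value, spikes add a magnitude at one tick, and the
returned mask labels exactly the altered ticks (overlapping faults on one
tick are rejected as ambiguous). Tube campaigns draw reported values
`truth * (1 + e)` with `e ~ N(0, rel_sd^2)`; the default
`tube_noise_rel_sd = 0.075` places ~95 percent of single-tube errors within
±15 percent, the middle of the ±10–20 percent range quoted for tubes in the
literature. Follow-up truths at the intervention site are reduced by
`intervention_delta` (default 8 ug/m3 at one of six sites).

Two deliberate simplifications matter for interpreting test results. First,
per-location truths are constant across months by default. Seasonal truth
variation is common to both month-matched periods, so it cancels in the
difference of group means but inflates both group variance estimates: Welch
intervals on seasonally varying truths are conservative (coverage above
nominal). Constant truths give the nominal-coverage regime in which CI
calibration can actually be checked. Second, "clean data" scenarios
(capture = 100 percent) use a purely deterministic latent signal
(`episodic_sd = 0`, diurnal amplitude 3, small noise): with episodic
variation on, a 3-MAD monthly filter legitimately removes a fraction of true
extremes — as it would on real data — so a 100-percent-capture identity is
only meaningful on a series with no removable values by construction.

What the generator does **not** emulate: meteorology-driven sensor bias
(hygroscopic growth and the manufacturer's undisclosed calibration),
particle-composition effects, long-term drift, traffic or dispersion
physics, and spatial structure beyond the shared/local decomposition.
Passing tests demonstrate that the pipeline implements its stated rules and
recovers known injected structure; they do not validate the sensors
themselves or any causal claim about interventions.

## Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` use one-year single-site runs for
fault recovery (20 seeds), a 4-site year for the clean-capture identity,
1,000 replicate tube campaigns (6 locations, 4 matched months, triplicates)
for CI coverage/detection/false-positive rates, 10,000 tubes for the
single-tube error share, and 500 random arrays (length <= 200) for
brute-force oracle equivalence of Steps 3–4 — sizes at which Monte-Carlo
error is small relative to the tolerances tested while a full run stays in
the minutes range on one CPU. Timestamps are interval-start, timezone-naive
UTC throughout; hours are half-open `[h, h + 1)`; days and months are
calendar units in UTC. CSV interchange uses ISO 8601 timestamps and
fixed 6-decimal concentrations so writer/reader pairs round-trip
bit-identically.

## Known limitations

- Step 2 interprets the low-RH keep-rule literally; users following the
  high-RH masking convention must set `rh_min`/`rh_max` accordingly.
- Capture denominators count all clock hours in the period, including hours
  lost to meteorology masking; if "potential" is meant net of envelope
  violations the percentages will differ.
- The intervention comparison is descriptive: month-matching controls season
  only coarsely, and no traffic or meteorology covariates are adjusted for,
  so significance does not establish attribution.
- Percentile and exceedance statistics are computed on hourly averages;
  computing them on 15-minute data would change extremes and tails.
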