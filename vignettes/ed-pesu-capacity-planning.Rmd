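---
title: "Modelling ED/PESU patient flow: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ED/PESU patient flow: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pesuflow` studies capacity planning for an emergency department (ED) that
operates a Psychiatric Emergency Services Unit (PESU) — a small secure area
(six spaces at baseline) to which medically stable mental-health-and-addiction
(MHA) patients are routed from triage. This vignette documents the model, its
assumptions, the tunable parameters, the synthetic-data generator, and the
design choices made where the problem was genuinely open. Code examples are
kept small; the package's test suite and `scripts/acceptance.R` run the
full-scale versions.

## The patient-flow model

Patients arrive in ten independent homogeneous Poisson streams: non-MHA
(NMHA), the five substance-abuse subgroups (alcohol, opioid, cannabis,
multiple substances, other substances), and the four other MHA conditions
(schizophrenia, mood, anxiety, others). Each arrival draws, from its class's
distributions, a CTAS acuity level (1–5), a discharge disposition, and a
total treatment requirement $T$ (lognormal, stratified by class and
disposition — the strata the input-modelling stage fits from visit records).

Flow rules:

* **NMHA and PESU-ineligible MHA patients** join a single FIFO queue for the
  ED's beds (32 at baseline). A patient holds a bed for $\beta T$, where
  $\beta \in (0,1]$ is the *bed-holding scale*; their length of stay (LOS)
  is $\text{wait} + T$. The remaining $(1-\beta)T$ represents
  assessment/waiting-room/results time that does not occupy a monitored bed.
  Without this split, treating the historical LOS distribution directly as
  bed occupancy offers roughly 46 bed-hours per hour to 32 beds — an
  infeasible load — so $\beta$ is both a structural necessity and the LOS
  calibration knob.
* **Eligible MHA patients** (eligible with probability `pesu_eligibility`,
  i.e. medically stable and not requiring a monitored bed) enter the PESU
  immediately if a space is free and hold it for a triangular-distributed
  stay; their LOS is that stay.
* **Eligible MHA patients finding the PESU full** follow the ED path *and*
  join a FIFO transfer list. If a PESU space frees while they still queue
  for, or hold, an ED bed, they release the ED resource instantly, move to
  the PESU for a freshly drawn triangular stay, and count as PESU-treated.
  The fresh draw is a bookkeeping convention (remaining-work accounting is
  unknowable from aggregate data); its only visible consequence is a
  seconds-scale perturbation of mean LOS when beds are added (see
  *Direction tests* below).

Simultaneous events are ordered by (time, creation sequence); arrivals
precede same-instant releases. Each replication simulates one year
(8,760 h) with a 504 h (three-week) warm-up: LOS and PESU-share statistics
only accumulate for patients arriving after warm-up, while arrival counts
are reported over the full year so they are comparable with annual demand.
Patients still in the system at the horizon are censored (excluded from LOS
means, counted separately). Experiments run 20 replications by default and
report per-KPI means with 95% *t* confidence intervals.

The two headline KPIs are the **mean overall ED LOS** (patient-weighted over
all completed visits, NMHA and MHA alike) and the **PESU share** — MHA
patients treated in the PESU as a percentage of MHA arrivals.

## Randomness and common random numbers

All stochastic inputs are pre-drawn in R from per-stream substreams derived
from the replication seed: exponential arrival gaps, plus one row of six
uniforms per arrival (CTAS, disposition, service quantile, eligibility,
two triangular stay quantiles), transformed by inverse CDFs. The C++ event
engine is then fully deterministic. Consequences:

* identical (parameters, seed) pairs give bit-identical replications;
* scenarios are exactly common-random-number (CRN) coupled: changing an
  arrival rate rescales the *same* exponential gaps (a deterministic
  thinning, distributionally equivalent to removing each arrival
  independently), and changing a capacity reuses identical draws, so paired
  scenario-minus-baseline deltas isolate the scenario effect.

## Synthetic visit histories

No patient-level data ship with the package; `default_synthetic_config()` +
`generate_visit_history()` emulate a five-fiscal-year registry extract
(April 2012 – March 2017, 8,760 h per year, uniform timestamps within the
year). What it reproduces exactly: the published first/last-year annual
volumes for every category and substance subgroup (e.g. NMHA
52,422 → 58,947; alcohol 1,569 → 2,119; MHA totals 3,923 → 6,131), with
intermediate years linearly interpolated; per-category mean LOS (NMHA 6.1 h,
substance 6.2 h, schizophrenia 14.4 h, mood 12.1 h, anxiety 4.0 h, others
8.9 h), with the two published discharged-stratum means (substance 5.8 h,
NMHA 4.0 h) anchored and the other dispositions solved so the weighted
category mean is preserved.

What is invented, documented, and exposed in the config rather than silently
assumed: the CTAS mix (mass centred on level 3), the disposition mix
(discharged majority), the LOS coefficient of variation (1.0 per category,
typical for ED LOS), the 2012 volumes of the non-substance MHA conditions
(schizophrenia held flat at 484 — its series is stationary — and the
remaining 1,602 of the known 2012 MHA total split over mood/anxiety/others),
and the lognormal family for LOS. The generator does **not** reproduce
diurnal or seasonal arrival patterns (the model fits a single exponential
per class), the 2015 coding-standard dip, ambulance/walk-in distinctions, or
any patient covariates beyond the listed fields — so passing tests validate
the pipeline's statistical machinery on data *like* the hospital's, not the
hospital's idiosyncrasies.

## Input modelling

`categorize_icd()` implements the ICD-10 grouping (substance F55, F10–F19
with subgroups; schizophrenia F20 excluding F20.4, F21–F25, F28–F29; mood
F30–F34, F39; anxiety F40–F45, F48; others F50–F54, F59–F60, F63–F66,
F68–F69, X60–X84; everything else NMHA) with three-character-root range
semantics and the F20.4 exclusion tested before the F20 inclusion.
Interarrival fits are exponential maximum likelihood (window / count);
service fits are lognormal, method-of-moments by default (maximum likelihood
on logs behind a flag), over class × CTAS × disposition strata with
hierarchical fallback (→ class × disposition → class) for strata under two
records, each fallback logged. LOS distributions get a class dimension
because class-specific LOS means are reported and the simulator
differentiates classes; pooling across classes would erase exactly the
heterogeneity the scenarios manipulate.

## Forecasting

Annual demand is forecast with a five-method battery — OLS linear regression
and Holt's linear trend method for trending series; simple exponential
smoothing, moving average, and weighted moving average (flat multi-step
forecasts) for stationary series — selected by minimal in-sample
mean absolute deviation (MAD) of one-step fitted errors, ties broken by
candidate order (trend methods first). Points without a fitted value are
excluded from the MAD: none for regression, the two Holt initialization
points ($l_1 = y_1$, $b_1 = y_2 - y_1$), the first point for simple
smoothing, the first $k$ for window methods. Smoothing constants default to
0.5. The published weighted-moving-average weights (0.2, 8.0, 0.8) cannot
sum to one and are treated as raw weights, normalized with the raw pair
logged. Negative extrapolations are clamped to zero with a message. The
scenario stages consume the published forecast table
(`default_forecast_table()`) directly, because the intermediate-year series
behind the original forecasts was never published.

## Calibration

Two model quantities are unpublished and must be tuned so the baseline
reproduces the historical validation targets (overall LOS 6.2 h with
interval [5.9, 6.4]; PESU share 37.9% ± 1 pp; NMHA/MHA LOS reported
alongside): the bed-holding scale $\beta$ and the PESU stay distribution.
`calibrate_baseline()` runs a staged CRN bisection: stage one moves the
share into its band (share is monotone decreasing in stay length at fixed
capacity), stage two moves the LOS (monotone increasing in $\beta$), and
the stages iterate to joint convergence. Monotonicity is probed empirically
(three points per knob) before bisecting; a material reversal aborts with
diagnostics. A stage accepts the first knob value whose KPI enters its
interval; the share stages demand the interior of the band (0.55 pp margin)
because the search runs on 8 replications while the final experiment uses
20, and an edge value would drift out on re-estimation.

The two-knob search cannot converge with every MHA arrival PESU-eligible,
for a structural reason worth recording: PESU utilization obeys
$\text{util} = \text{share} \times \lambda_{\text{MHA}} \times \bar S / c$,
so a 37.9% share at $c = 6$ forces the mean stay $\bar S$ toward ~22.6 h as
the unit saturates, and stays that long push the overall LOS (which counts
PESU stays in full) above its 6.4 h ceiling. The search therefore detects
the failure and exposes the PESU *eligibility probability* as the share
knob — the documented third knob — with the stay restored to its default
triangular (min 1, mode 6, max 17 h; mean 8 h, chosen so the implied MHA
LOS mix matches the validated 7.7 h). The calibrated baseline lands near
eligibility ≈ 0.38 and $\beta ≈ 0.53$ (ED utilization ≈ 0.73), and meets
all four validation targets. Any calibrated triple is one of several
observationally equivalent choices; the package treats the calibration
report, not the knob values, as the meaningful output.

## Scenarios and direction tests

Scenario builders are pure transformations of the calibrated baseline:
**A** replaces class rates with the forecast table (substance subgroups
scaled proportionally within the aggregate); **B** thins the alcohol and
opioid streams by 10/30/45/63%; **C** adjusts cannabis by +19% (year 1) and
then −27% applied sequentially to the year-1 level, mirroring the two-year
post-legalization history it emulates; **D** adds PESU spaces (7–10); **E**
composes
A and D. Suites run against a single CRN baseline and report paired deltas.

Because several ladder effects are genuinely near zero in the calibrated
(unsaturated-PESU) regime — see the utilization identity above — the
package's direction tests assert monotonicity up to small
practical-equivalence margins: 0.02 h for LOS and 0.2 percentage points for
share, two orders of magnitude below any effect reported as operationally
meaningful. A strict floating-point inequality on a ~zero stochastic effect
would be decided by Monte-Carlo noise rather than by the model.

## Numerical choices and degenerate inputs

Hours are the single time unit; annual rates convert to hourly rates once
at the engine boundary (8,760 h per year). Zero-rate streams produce no
arrivals and vanish from every statistic. A PESU capacity of zero disables
the unit (utilization reported as NA). Zero-variance LOS strata yield a
flagged degenerate lognormal ($\sigma_{\log} = 0$). Proportion vectors must
sum to one within $10^{-9}$; parameter files store full 17-digit precision
so they round-trip. Event ties are resolved by creation order, arrivals
first. Replication seeds are `base_seed + 0 … n − 1`; substream seeds are
drawn from a seeded `sample.int`, keeping everything below $2^{31}$.

## Problem sizes used by the tests

The unit suite exercises the engine oracles (M/M/1 sojourn agreement within
3 standard errors, the infinite-server identity LOS ≡ T, flow conservation
and capacity bounds on full traces) at 8–20 thousand simulated hours per
replication, and runs searches on a 1/40-scale hospital; the acceptance
suite runs the full-scale calibration plus 20-replication experiments and
10-replication scenario suites. These sizes give sampling errors well below
every asserted tolerance while keeping a full run in the low minutes.

## Known limitations

Staff (physicians, nurses, social workers) and ancillary services are not
modelled as resources — consult/lab/imaging time is folded into $T$ — so
bed counts are the only capacity levers. There is no balking, reneging, or
ambulance-offload interaction. Arrivals are time-homogeneous within a year.
The PESU stay distribution and eligibility probability are calibrated, not
observed, and are identifiable only jointly; conclusions that depend on the
saturation state of the PESU (rather than on the validated KPIs) should be
drawn with care, as the validation targets themselves pin the unit to an
unsaturated operating point.
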