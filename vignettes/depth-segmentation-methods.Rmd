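---
title: "Methods: bathymetric segmentation of acoustic telemetry depth records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bathymetric segmentation of acoustic telemetry depth records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Passive acoustic telemetry of coastal fish produces long, irregular streams
of detections: a tagged fish's pressure-sensing transmitter emits a coded
signal roughly every two minutes, and any moored receiver within range logs
the time and the sensor depth. From such logs — here modelled on a
multi-year study of brown meagre (*Sciaena umbra*) in a NW Mediterranean
marine protected area — one wants to know how individuals distribute
themselves through the water column over the day and over the year, and how
that distribution responds to temperature and to the seasonal thermocline.

`bathyseg` implements that analysis chain end to end:

1. **Telemetry processing** — ingest detection logs, average depth per fish
   and clock hour, compute residence metrics, flag early dropouts, label
   hours day/night from solar ephemerides.
2. **Thermocline estimation** — fit a four-parameter logistic to each
   vertical thermistor profile and locate the mid-depth of the thermocline.
3. **Segmentation** — standardize depth to Z-scores, split individuals into
   a shallow-resident (SS) and a seasonally shifting (DS) group, and
   classify warm versus cold months.
4. **Activity** — use the day/night variance of depth as a proxy of
   vertical activity.
5. **Models** — linear mixed models with per-fish residual variances, and
   penalized-smooth (GAMM-style) covariate effects.
6. **Synthetic data** — a generator that emulates the statistical structure
   of the study, so every stage is testable without the (undeposited)
   field data.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers that call the package
functions and write tables under `results/`; all computation lives in the
package so the tests and the acceptance script exercise the same code.

## Telemetry processing

Hourly averaging uses the arithmetic mean of detection depths per fish and
civil clock hour. Daily and hourly binning use local civil time at the site
(`Europe/Paris`, fixed offset +1/+2 h with DST) for comparability with
local sunrise and sunset; stored instants remain UTC. Hours without
detections are absent rather than zero-filled.

The residence index is the fraction of monitored days with at least one
detection, with the tracking period taken as the metadata end date minus
the tagging date in whole days — the end date is treated as authoritative
(whether monitoring windows were battery- or study-limited cannot be
recovered from a log). Detections per day divide the total detection count
by the tracking period (not by days detected); this is the only convention
consistent with the packaged field-study summary table, e.g. 39,904
detections over 504 days reported as 79/day. Report columns round half-up
(index to 2 decimals, rate to an integer).

Fish that disappear shortly after release are excluded by a span rule —
last detection fewer than `min_span_days` (default 30) days after tagging —
with an explicit exclusion list available as an override for studies where
the excluded individuals are known.

Sunrise and sunset come from the NOAA solar-calculator equations
(Julian-century polynomials for mean solar longitude and anomaly, equation
of center, apparent longitude, corrected obliquity, and the hour angle at
zenith 90.833°), evaluated first at solar noon and once more at the event
time. Agreement with an independent brute-force ephemeris is a few seconds;
the tests require 2 minutes. Latitudes poleward of the polar circles are
rejected rather than approximated. An hour is "day" when its midpoint falls
in `[sunrise, sunset)`.

## Thermocline estimation

Each thermistor profile (8 sensors, 5–40 m at 5 m steps by default) is fit
with the four-parameter logistic

$$T(z) = T_{deep} + \frac{T_{shallow} - T_{deep}}{1 + \exp((z - z_{mid})/s)},$$

the standard smooth single-thermocline profile shape and the natural
four-parameter choice given that the method needs a unique
steepest-gradient point; alternative forms could be swapped in behind the
same interface. Fitting is nonlinear least squares (Levenberg–Marquardt)
with multi-start initialization: asymptotes from the shallowest/deepest
sensors, mid-depth from the steepest finite-difference pair, and scale
starts $s \in \{1, 3, 10\}$ m, with bounds $s > 0.1$ m and $z_{mid}$ inside
the sensor span. The best start by residual sum of squares wins (ties at
$10^{-8}$ keep the earlier start). Fits that fail from every start are
flagged and excluded downstream — in practice this happens only for
near-isothermal winter profiles where the logistic is unidentifiable.

The fitted curve is evaluated on a 0.1 m grid spanning (and including) the
sensor extremes, and the **mid-depth** is the grid argmax of the analytic
$|dT/dz|$; for a converged logistic this equals $z_{mid}$ to within one
grid step, but the grid convention keeps the definition meaningful for any
pluggable profile shape. A thermocline is declared **present** only when
the temperature difference between the shallowest and deepest *measured*
sensors exceeds 3 °C; otherwise the mid-depth is undefined. Temperature at
an arbitrary depth (e.g. the 15 m covariate series) evaluates the fitted
model when the fit converged and interpolates linearly between bracketing
sensors otherwise.

Profiles are fitted individually and aggregated to daily means of present
mid-depths afterwards; whether one should average profiles within a day
before fitting is ambiguous, and per-profile fitting preserves the
presence gate's meaning (a day can be partly stratified).

## Segmentation

Z-scores are computed **globally** — one mean and one SD over all included
fish-hours jointly — not per fish: per-fish scaling would force every
fish's total mean Z to zero and make clustering on per-fish means
meaningless. By default the standardized variable is the signed *elevation*
(−depth), so positive Z means shallower than the population average. This
orientation is what makes the warm-period rule ("months with at least 3
fish showing positive mean Z") select the shallow, warm-season months; the
opposite orientation is available as an option.

The SS/DS split is an **exact one-dimensional two-means**: per-fish total
mean Z-scores are sorted and every cut point is scanned for the partition
minimizing the within-cluster sum of squares. In one dimension the optimal
two-means partition is always an interval split, so the scan is exact,
deterministic, and order-invariant (the test suite checks it against
exhaustive search over all two-partitions for up to 10 fish). The cluster
with the larger mean Z (shallower fish) is labelled SS.

Warm months are classified from the DS group only, following the rule
literally: a month — pooled across calendar years — is warm when at least
`min_fish` (default 3) DS fish have strictly positive mean Z that month.
No contiguity is enforced; on both the synthetic cohorts and the study's
reported outcome the rule yields the contiguous April–August set.

## Activity proxy

Activity is the sample variance (denominator $n-1$) of *hourly mean*
depths within each (fish, date, day/night) cell — computed on hourly means
rather than raw detections for consistency with the hourly analysis grain,
and unweighted by detection count (both choices configurable in principle;
the raw-detection variant would mix transmission-rate variation into the
behavioural signal). Cells with fewer than `min_hours = 3` hourly values
are dropped so every variance has at least 2 degrees of freedom. Monthly
summaries average $\ln(x+1)$ of the variance per group × phase × month,
months pooled across years.

## Models

The depth and activity mixed models are

$$y_{ij} = X_{ij}\beta + a_i + \varepsilon_{ij}, \qquad
  a_i \sim N(0, \tau^2), \qquad \varepsilon_{ij} \sim N(0, \sigma_i^2),$$

with $y$ the $\ln(x+1)$-transformed depth (hourly) or depth variance
(daily, per phase), fish $i$ as a random intercept, and a separate residual
variance per fish (`varIdent`) to absorb the strong between-individual
heteroscedasticity; "homogeneity within fish" is read as each fish's
residual variance being constant across covariates. Estimation is maximum
likelihood whenever fits feed likelihood-ratio tests (REML is available for
final estimates); the LRT compares nested ML fits by
$\chi^2 = 2\Delta\ell$ with the free-parameter-count difference as degrees
of freedom. Factor baselines are cold period, day phase and the DS group,
so coefficient signs read directly as warm/night/SS contrasts. Year is
never a model term (different fish were tagged in different years).
Coefficient p-values use the residual-df convention of the underlying
`nlme` machinery. Model backends are `nlme::lme`/`gls` and `stats::lm`;
the package adds the specification layer, the variance-component
extraction, and the LRT bookkeeping.

Smooth covariate effects (temperature at 15 m; thermocline mid-depth on
present days only) are penalized cubic regression splines with basis
dimension $k = 10$ (a documented default — large enough that the penalty,
not the basis, controls wiggliness), second-derivative penalty, and the
smoothing parameter chosen by GCV, fitted jointly with the fish random
intercept through the random-effect-smooth representation in `mgcv::gam`.
The returned curve is the centred smooth on a 100-point covariate grid
with pointwise, bias-uncorrected 95% bounds. Fewer than 20 distinct
covariate values is an error (the basis would be unidentifiable).
Simple group/period contrasts use a two-way factorial ANOVA on hourly mean
depth and a Kruskal–Wallis test of cold-period monthly means across DS
individuals.

## The synthetic cohort generator

The generator's defaults *are* the study conditions: 20 tagged fish = 8
shallow-resident + 9 seasonally shifting + 3 early dropouts; SS seasonal
mean depths 8.02 m (cold) / 7.53 m (warm); DS group means 22.5 m (cold) /
12 m (warm) with warm months April–August; a ~2-min transmission cycle
with ±10% jitter; a June–November thermocline over a 11.5–23 °C seasonal
surface sinusoid sampled by 8 thermistors at 5–40 m.

Values the study does not pin down were chosen once, on field-realism
grounds, and not revisited:

* **Detection probability 0.2** — reported detection rates of roughly
  80–340 per day against the 720/day transmission cycle.
* **Within-day noise**: a discrete mean-reverting AR(1) (Ornstein–Uhlenbeck
  style) depth process with a 1 h reversion timescale and stationary SD
  1.5 m. No micro-movement model can be inferred from the study; this
  stand-in makes hourly means well-defined and the variance controllable,
  and implies nothing about the fish.
* **DS cold-period stratification**: individual cold means sit on an
  evenly spaced grid centred exactly on the 22.5 m group mean with
  between-fish SD 4 m, reproducing the reported depth stratification among
  DS individuals while keeping the group mean exact.
* **Diel offset 1.5 m, dusk excursion 6 m** in June–July, dropout window
  ≤ 10 days, bottom 45 m, deep-water temperature 12 °C, thermocline
  mid-depth drifting 10 → 30 m across the season within a configured
  8–35 m band (kept inside the sensor span so profile fits remain
  well-posed).

Two constructions keep the configured period means *exactly* recoverable
rather than approximately: the day/night offset is weighted by the actual
day and night duration of each date (day hours sit `+A·night_frac` deep,
night hours `−A·day_frac`), and the pre-sunset dusk excursion is
mean-compensated across the remaining daytime minutes of the same date.
Each date's mean depth therefore equals the seasonal mean by construction,
so deviations of recovered period means from configuration are pure
sampling error — which is what the recovery tests assert (within two
fish-level simulation standard errors). Replication during development
confirmed the estimator is unbiased (mean deviation indistinguishable from
zero across independent seeds).

What the generator deliberately does **not** emulate: receiver geometry,
range and propagation loss (detection is a single Bernoulli rate);
horizontal movement; autocorrelated detection gaps (weather, biofouling);
internal-wave or multi-layer thermocline structure; tag loss or mortality
other than the early-dropout window. Passing recovery tests therefore
demonstrates that the pipeline's inference logic is correct under the
study's statistical structure — not that it is robust to every field
pathology.

## Problem sizes and numerical conventions

The test suite runs small cohorts (3–7 fish, weeks to one year) for module
tests and the full 17–20-fish, one- and two-year conditions for the
recovery checks; the acceptance script simulates one 17-fish year and one
20-fish two-year cohort. The analysis scripts use a one-year cohort and
thin the hourly table to 40,000 rows for the mixed-model stage, which
leaves over 2,000 observations per fish while keeping the per-fish
variance estimation quick. Convergence tolerances: `ftol = 1e-10` in the
profile fits (RSS scale), `lme` defaults (~1e-6 relative) for mixed
models; the thermocline evaluation grid is inclusive of both span
endpoints; two-means ties break deterministically toward the first optimal
cut; report rounding is half-up.

## Known limitations

* The two-group split is hard-coded as exactly two clusters; no $k > 2$
  model selection is attempted.
* The thermocline model assumes a single pycnocline-like feature; profiles
  with two stratified layers will be summarised by whichever gradient
  dominates the fitted logistic.
* Mixed-model degrees of freedom follow the `nlme` convention; no
  Satterthwaite/Kenward–Roger adjustment, and no residual autocorrelation
  structures are offered.
* The warm/cold rule consults the DS group only, as specified; a cohort
  with no DS fish has no defined period structure.
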