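# bathyseg

Bathymetric distribution analysis of acoustically tagged coastal fish.

Passive acoustic telemetry follows individual fish for months to years: an
implanted transmitter with a pressure sensor emits a coded signal every
couple of minutes, and moored receivers log each detection with the fish's
depth. `bathyseg` turns such detection logs — modelled on a multi-year
brown meagre (*Sciaena umbra*) study in a Mediterranean marine protected
area — into the study's standard analysis products:

* **Residence & hourly depth** — per-fish tracking summaries (days
  detected, residence index = days detected / days monitored, detections
  per day), hourly mean depth series, early-dropout exclusion, and
  day/night labels from the NOAA solar-calculator ephemeris.
* **Thermocline** — per-profile fits of the four-parameter logistic
  `T(z) = T_d + (T_s − T_d) / (1 + exp((z − z_mid)/s))` to thermistor
  strings; the thermocline mid-depth is the steepest-gradient point of the
  fitted curve on a 0.1 m grid, reported only when the surface-to-deep
  temperature difference exceeds 3 °C.
* **Segmentation** — depth standardized to global Z-scores on the
  elevation scale (positive Z = shallower than average); an exact
  one-dimensional two-means split of per-fish mean Z into shallow-resident
  (SS) and seasonally shifting (DS) groups; warm months classified as
  those where ≥ 3 DS fish have positive monthly mean Z.
* **Activity** — the sample variance of hourly depth within each
  (fish, date, day/night) cell as a vertical-activity proxy, summarised
  monthly on the ln(x+1) scale.
* **Models** — linear mixed models
  `y_ij = Xβ + a_i + ε_ij`, `a_i ~ N(0, τ²)`, `ε_ij ~ N(0, σ_i²)`
  with per-fish residual variances and likelihood-ratio tests between
  nested ML fits, plus penalized cubic-spline smooths (basis dimension 10,
  GCV) of temperature and thermocline mid-depth fitted jointly with the
  fish random intercept.
* **Synthetic cohorts** — a generator whose defaults encode the study's
  structure (8 SS + 9 DS + 3 dropout fish, SS at 8.02/7.53 m, DS at
  22.5/12 m across an April–August warm period, ~2-min transmission
  cycle, June–November thermocline), so the whole pipeline is testable
  without the undeposited field data.

## Worked example

Simulate a small one-year cohort and run the pipeline:

```r
library(bathyseg)

cfg <- cohort_config(n_ss = 3, n_ds = 4, dropout_fish = 1,
                     start_date = "2017-01-01", end_date = "2017-12-31",
                     seed = 7)
sim <- simulate_cohort(cfg)
pl  <- run_depth_pipeline(sim$detections, sim$metadata)

pl$segmentation
#> Cohort segmentation
#>   fish:7 (SS 3 / DS 4)
#>   warm months: Apr, May, Jun, Jul, Aug

pl$period_summary$by_group_period
#>   group period mean_depth         se     n
#> 1    DS   cold  22.470760 0.03016565 20215
#> 2    DS   warm  11.996147 0.01297774 14672
#> 3    SS   cold   8.015571 0.01236480 15169
#> 4    SS   warm   7.531065 0.01482651 11003
```

The dropout fish is excluded by the 30-day span rule; the two-means split
recovers the generated archetypes; the warm months recovered by the
positive-Z rule are exactly the generated April–August set; and the
group × period mean depths recover the configured 22.5 / 12 / 8.02 / 7.53 m
within sampling error. `fish_summary_fixture()` loads the packaged
field-study tagging table (20 fish, two capture sites) with the residence
columns recomputed from raw counts.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` writes synthetic detection, metadata and
thermistor CSVs; `02_residence.R` through `06_models.R` produce the
residence table, thermocline series, segmentation, activity summaries and
the mixed/smooth model tables under `results/`.

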