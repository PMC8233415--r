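#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Simulates one tracking year of the default cohort (8 shallow-resident SS
# fish, 9 seasonally shifting DS fish, 3 early dropouts, ~2-min transmitter
# cycle thinned at the default detection probability) plus a year of daily
# noon thermistor profiles, and writes the three raw CSVs every later stage
# consumes. One year keeps the downstream model fits quick while preserving
# every structural feature (both periods, the thermocline season, the dusk
# peak); rerun with a 2-year window by editing `end_date`.

library(bathyseg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 42L

cohort <- cohort_config(start_date = "2016-06-01", end_date = "2017-06-01",
                        seed = seed)
cat(sprintf("cohort: %d SS + %d DS + %d dropouts, %s to %s, seed %d\n",
            cohort$n_ss, cohort$n_ds, cohort$dropout_fish,
            cohort$start_date, cohort$end_date, seed))
sim <- simulate_cohort(cohort)
cat(sprintf("simulated %s detections from %d fish\n",
            format(nrow(sim$detections), big.mark = ","),
            length(unique(sim$detections$transmitter_id))))

ocean <- ocean_config(seed = seed)
times <- as.POSIXct(paste(seq(cohort$start_date, cohort$end_date - 1,
                              by = "day"), "12:00:00"), tz = "UTC")
thermo <- simulate_thermistors(ocean, times)
cat(sprintf("simulated %d daily thermistor profiles (%d sensors)\n",
            length(times), length(ocean$sensor_depths)))

write_detections_csv(sim$detections, "results/data/detections.csv")
write_metadata_csv(sim$metadata, "results/data/fish_metadata.csv")
write_thermistors_csv(thermo, "results/data/thermistors.csv")
cat("wrote results/data/{detections,fish_metadata,thermistors}.csv\n")
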