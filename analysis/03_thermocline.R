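#!/usr/bin/env Rscript
# Stage 3: thermocline estimation from the thermistor string.
#
# Fits the four-parameter logistic to every daily profile, derives the
# mid-depth (steepest-gradient point on a 0.1 m grid), applies the 3 degC
# presence gate, and extracts the 15 m temperature series used later as the
# smooth-model covariate.

library(bathyseg)

thermo <- read.csv("results/data/thermistors.csv")
thermo$timestamp <- as.POSIXct(thermo$timestamp,
                               format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

ser <- thermocline_series(thermo)
write.csv(ser, "results/thermocline_series.csv", row.names = FALSE)

months <- as.POSIXlt(ser$timestamp)$mon + 1
pres_months <- sort(unique(months[ser$present]))
cat(sprintf("thermocline present in months: %s\n",
            paste(month.abb[pres_months], collapse = ", ")))
cat(sprintf("mid-depth range when present: %.1f-%.1f m\n",
            min(ser$mid_depth[ser$present], na.rm = TRUE),
            max(ser$mid_depth[ser$present], na.rm = TRUE)))

daily <- daily_thermocline(ser)
write.csv(daily, "results/thermocline_daily.csv", row.names = FALSE)

# 15 m temperature per profile (model evaluation, interpolation fallback)
t15 <- vapply(split(thermo, thermo$timestamp), function(p) {
  temp_at_depth(fit_profile(p$depth_m, p$temp_c), 15)
}, numeric(1))
t15 <- data.frame(date = as.Date(names(t15)), temp_15m = unname(t15))
write.csv(t15, "results/temperature_15m.csv", row.names = FALSE)
cat(sprintf("15 m temperature: %.1f-%.1f degC over the year\n",
            min(t15$temp_15m), max(t15$temp_15m)))
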