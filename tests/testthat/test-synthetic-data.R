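test_that("noise-free single SS fish tracks sit exactly on the seasonal means", {
  cfg <- cohort_config(n_ss = 1, n_ds = 0, dropout_fish = 0,
                       start_date = "2017-03-25", end_date = "2017-04-08",
                       diel_amplitude_m = 0, depth_sd_within = 0,
                       dusk_excursion_m = 0, seed = 3)
  tr <- simulate_true_tracks(cfg)
  d <- tr$depth[[1]]
  day_idx <- rep(seq_len(tr$n_min / 1440), each = 1440)
  months <- as.POSIXlt(cfg$start_date + day_idx - 1)$mon + 1
  expect_true(all(d[months == 3] == cfg$ss_mean_depth_cold))
  expect_true(all(d[months == 4] == cfg$ss_mean_depth_warm))
})

test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_ss = 0, n_ds = 0), "at least one fish")
  expect_error(cohort_config(start_date = "2018-01-01",
                             end_date = "2017-01-01"), "precede")
  expect_error(cohort_config(bottom_depth = 10), "shallower")
  expect_error(cohort_config(detection_prob = 1.5), "detection_prob")
})

test_that("DS cold-month track mean matches the configured 22.5 m group mean", {
  cfg <- cohort_config(n_ss = 2, n_ds = 3, dropout_fish = 0,
                       start_date = "2017-01-01", end_date = "2017-07-01",
                       seed = 5)
  tr <- simulate_true_tracks(cfg)
  day_idx <- rep(seq_len(tr$n_min / 1440), each = 1440)
  months <- as.POSIXlt(cfg$start_date + day_idx - 1)$mon + 1
  cold <- !(months %in% cfg$warm_months)
  ds <- tr$meta$fish_id[tr$meta$archetype == "DS"]
  cold_mean <- mean(vapply(ds, function(f) mean(tr$depth[[f]][cold]),
                           numeric(1)))
  expect_equal(cold_mean, 22.5, tolerance = 0.01)
})

test_that("track simulation is deterministic in the seed", {
  cfg1 <- noiseless_cohort(seed = 9)
  cfg1$depth_sd_within <- 1.5
  tr_a <- simulate_true_tracks(cfg1)
  tr_b <- simulate_true_tracks(cfg1)
  expect_identical(tr_a$depth, tr_b$depth)
  cfg2 <- cfg1
  cfg2$seed <- 10L
  tr_c <- simulate_true_tracks(cfg2)
  expect_false(identical(tr_a$depth, tr_c$depth))
})

test_that("detection counts follow the transmission and thinning model", {
  # deterministic limit: p = 1, no jitter, one day, 120 s cycle -> 720
  cfg <- noiseless_cohort()
  cfg$end_date <- as.Date("2017-01-02")
  tr <- simulate_true_tracks(cfg)
  det <- simulate_detections(tr, cfg)
  expect_equal(nrow(det), 720L)

  # p = 0 -> empty stream
  cfg0 <- cfg
  cfg0$detection_prob <- 0
  expect_equal(nrow(simulate_detections(tr, cfg0)), 0L)

  # binomial thinning: mean daily count over 30 days within 3 SD
  cfgb <- noiseless_cohort(seed = 21)
  cfgb$end_date <- as.Date("2017-01-31")
  cfgb$detection_prob <- 0.2
  cfgb$jitter_frac <- 0.1
  trb <- simulate_true_tracks(cfgb)
  detb <- simulate_detections(trb, cfgb)
  daily <- table(as.Date(format(detb$timestamp, "%Y-%m-%d", tz = "UTC")))
  expect_equal(length(daily), 30L)
  expected <- 720 * 0.2
  se_mean <- sqrt(720 * 0.2 * 0.8 / 30)
  expect_lt(abs(mean(daily) - expected), 3 * se_mean)

  # z-test of the total count against Binomial(n_candidates, p), alpha = 0.01
  n_cand <- 30 * 720
  z <- (nrow(detb) - n_cand * 0.2) / sqrt(n_cand * 0.2 * 0.8)
  expect_lt(abs(z), qnorm(0.995))
})

test_that("dropout fish stop emitting within the post-release window", {
  cfg <- cohort_config(n_ss = 2, n_ds = 2, dropout_fish = 2,
                       start_date = "2017-01-01", end_date = "2017-03-01",
                       detection_prob = 0.3, seed = 13)
  sim <- quiet(simulate_cohort(cfg))
  spans <- tapply(as.Date(sim$detections$timestamp),
                  sim$detections$transmitter_id,
                  function(d) as.numeric(diff(range(d))))
  drop_ids <- sim$metadata$fish_id[sim$metadata$dropout]
  expect_true(all(spans[drop_ids] <= cfg$dropout_max_days))
  expect_true(all(spans[setdiff(names(spans), drop_ids)] > 50))
})

test_that("DS monthly mean depth is non-increasing from March to June", {
  cfg <- cohort_config(n_ss = 1, n_ds = 3, dropout_fish = 0,
                       start_date = "2017-03-01", end_date = "2017-07-01",
                       seed = 17)
  tr <- simulate_true_tracks(cfg)
  day_idx <- rep(seq_len(tr$n_min / 1440), each = 1440)
  months <- as.POSIXlt(cfg$start_date + day_idx - 1)$mon + 1
  ds <- tr$meta$fish_id[tr$meta$archetype == "DS"]
  pooled <- rowMeans(vapply(ds, function(f) tr$depth[[f]], numeric(tr$n_min)))
  mmean <- tapply(pooled, months, mean)[as.character(3:6)]
  expect_true(all(diff(mmean) <= 1e-9))
})

test_that("with zero noise the pipeline recovers configured means exactly", {
  cfg <- cohort_config(n_ss = 1, n_ds = 1, dropout_fish = 0,
                       start_date = "2017-02-01", end_date = "2017-02-08",
                       diel_amplitude_m = 0, depth_sd_within = 0,
                       dusk_excursion_m = 0, jitter_frac = 0,
                       detection_prob = 1, ds_cold_spread = 0, seed = 2)
  sim <- quiet(simulate_cohort(cfg))
  hourly <- quiet(hourly_mean_depth(sim$detections |>
    transform(fish_id = transmitter_id, depth = depth_m)))
  means <- tapply(hourly$mean_depth, hourly$fish_id, mean)
  expect_equal(unname(means["F01"]), cfg$ss_mean_depth_cold)
  expect_equal(unname(means["F02"]), cfg$ds_mean_depth_cold)
})

test_that("thermistor profiles respect the thermocline month set", {
  oc <- ocean_config(seed = 4)
  # one noon profile per week across a year
  times <- as.POSIXct(paste(seq(as.Date("2017-01-04"), as.Date("2017-12-28"),
                                by = "7 days"), "12:00:00"), tz = "UTC")
  prof <- simulate_thermistors(oc, times)
  pr <- split(prof, prof$timestamp)
  rng <- vapply(pr, function(p) diff(range(p$temp_c)), numeric(1))
  months <- as.POSIXlt(times)$mon + 1
  expect_true(all(rng[!(months %in% oc$thermocline_months)] < 3))
  expect_true(all(rng[months %in% oc$thermocline_months] > 3))
})

test_that("zero-sharpness limit gives a step profile at the drawn mid-depth", {
  oc <- ocean_config(thermocline_sharpness = 1e-9, noise_sd = 0, seed = 6)
  t1 <- as.POSIXct("2017-08-01 12:00:00", tz = "UTC")
  prof <- simulate_thermistors(oc, t1)
  truth <- attr(prof, "truth")
  above <- prof$temp_c[prof$depth_m < truth$z_mid]
  below <- prof$temp_c[prof$depth_m > truth$z_mid]
  expect_equal(unique(round(above, 6)), round(truth$surface_temp, 6))
  expect_equal(unique(round(below, 6)), round(oc$deep_temp, 6))
})

test_that("steepest sensor gradient lies nearest the configured mid-depth", {
  oc <- ocean_config(thermocline_depth_range = c(19, 21), noise_sd = 0.02,
                     seed = 8)
  t1 <- as.POSIXct("2017-09-01 12:00:00", tz = "UTC")
  prof <- simulate_thermistors(oc, t1)
  grad <- abs(diff(prof$temp_c) / diff(prof$depth_m))
  mids <- (prof$depth_m[-1] + prof$depth_m[-nrow(prof)]) / 2
  expect_equal(mids[which.max(grad)], 20, tolerance = 2.6)
})

test_that("cohort configuration round-trips through YAML", {
  skip_if_not_installed("yaml")
  tmp <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(n_ss = 2, n_ds = 3, detection_prob = 0.4,
                        start_date = "2017-01-01", end_date = "2017-06-01",
                        seed = 99), tmp)
  cfg <- read_cohort_config(tmp)
  expect_equal(cfg$n_ss, 2L)
  expect_equal(cfg$detection_prob, 0.4)
  expect_equal(cfg$start_date, as.Date("2017-01-01"))
  expect_equal(cfg$ds_mean_depth_cold, 22.5)  # defaults retained
  yaml::write_yaml(list(bogus_field = 1), tmp)
  expect_error(read_cohort_config(tmp), "unknown configuration")
})
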