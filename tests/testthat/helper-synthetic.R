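# Shared small synthetic fixtures, built once per test run.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# a deterministic, noise-free single-fish cohort (degenerate limits)
noiseless_cohort <- function(...) {
  defaults <- list(n_ss = 1, n_ds = 0, dropout_fish = 0,
                   start_date = "2017-01-01", end_date = "2017-01-08",
                   diel_amplitude_m = 0, depth_sd_within = 0,
                   dusk_excursion_m = 0, jitter_frac = 0,
                   detection_prob = 1, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# small mixed cohort spanning a full year (cached across tests)
.small_sim_env <- new.env()
small_sim <- function() {
  if (is.null(.small_sim_env$sim)) {
    cfg <- cohort_config(n_ss = 3, n_ds = 4, dropout_fish = 1,
                         start_date = "2017-01-01", end_date = "2017-12-31",
                         detection_prob = 0.2, seed = 11)
    .small_sim_env$sim <- c(quiet(simulate_cohort(cfg)), list(config = cfg))
  }
  .small_sim_env$sim
}

small_pipeline <- function() {
  if (is.null(.small_sim_env$pipe)) {
    sim <- small_sim()
    .small_sim_env$pipe <- quiet(
      run_depth_pipeline(sim$detections, sim$metadata))
  }
  .small_sim_env$pipe
}

# hourly-table constructor for unit tests that bypass the generator
make_hourly <- function(fish_id, date_local, hour, mean_depth,
                        tz = "Europe/Paris") {
  date_local <- as.Date(date_local)
  data.frame(
    fish_id = fish_id, date_local = date_local, hour = hour,
    hour_start = as.POSIXct(paste0(format(date_local), " ",
                                   sprintf("%02d", hour), ":00:00"), tz = tz),
    month = as.POSIXlt(date_local)$mon + 1L,
    mean_depth = mean_depth,
    n_detections = 1L
  )
}
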