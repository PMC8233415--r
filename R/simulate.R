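#' Simulate true depth tracks for a tagged cohort
#'
#' Generates one depth series per fish at 1-minute resolution over the study
#' window. Each fish carries an archetype label: `SS` fish hold the shallow
#' seasonal means year-round, `DS` fish move from an individual cold-period
#' mean (evenly stratified around the configured group mean) to the shared
#' warm-period mean during `warm_months`. All fish are shallower at night by
#' `diel_amplitude_m`; the day/night offset is weighted by the actual
#' day/night duration of each date so that the daily mean depth equals the
#' seasonal mean exactly. In `dusk_peak_months` a half-sine depth excursion
#' of amplitude `dusk_excursion_m` is injected in the hour before sunset and
#' mean-compensated across the remaining daytime minutes of the same date.
#' Within-day noise is a discrete mean-reverting (AR(1)) process with a 1-h
#' reversion timescale and stationary SD `depth_sd_within`. Depths are
#' clipped to `[0, bottom_depth]`.
#'
#' @param cohort A [cohort_config()].
#'
#' @return A list of class `"fish_tracks"`: `start` (POSIXct UTC), `n_min`,
#'   `depth` (named list of per-fish numeric vectors), `is_day` (logical per
#'   minute), and `meta` (per-fish metadata data.frame with the ground-truth
#'   columns `archetype`, `cold_mean`, `warm_mean`, `dropout`).
#' @export
simulate_true_tracks <- function(cohort) {
  validate_cohort_config(cohort)
  n_days <- as.integer(cohort$end_date - cohort$start_date)
  if (n_days < 1L) stop("study window must span at least one day")
  n_min <- n_days * 1440L
  start <- as.POSIXct(paste(format(cohort$start_date), "00:00:00"), tz = "UTC")
  dates <- cohort$start_date + seq_len(n_days) - 1L
  month_by_date <- as.POSIXlt(dates)$mon + 1L
  day_idx <- rep(seq_len(n_days), each = 1440L)

  # --- diel geometry -------------------------------------------------------
  ev <- solar_events(dates, cohort$site_lat, cohort$site_lon)
  sr_min <- as.numeric(difftime(ev$sunrise, start, units = "mins"))
  ss_min <- as.numeric(difftime(ev$sunset, start, units = "mins"))
  mid <- seq_len(n_min) - 0.5                     # minute midpoints from start
  is_day <- mid >= sr_min[day_idx] & mid < ss_min[day_idx]
  day_count <- tabulate(day_idx[is_day], nbins = n_days)
  night_count <- 1440L - day_count
  A <- cohort$diel_amplitude_m
  offset <- ifelse(is_day,
                   A * night_count[day_idx] / 1440,
                   -A * day_count[day_idx] / 1440)

  # --- dusk excursion (mean-compensated within the day phase) --------------
  bump <- numeric(n_min)
  if (cohort$dusk_excursion_m > 0 && length(cohort$dusk_peak_months)) {
    dusk_dates <- which(month_by_date %in% cohort$dusk_peak_months)
    in_dusk <- day_idx %in% dusk_dates &
      mid >= (ss_min[day_idx] - 60) & mid < ss_min[day_idx]
    u <- (mid - (ss_min[day_idx] - 60)) / 60
    bump[in_dusk] <- cohort$dusk_excursion_m * sin(pi * u[in_dusk])
    bump_sum <- tapply_sum(bump, day_idx, n_days)
    n_bump <- tabulate(day_idx[in_dusk], nbins = n_days)
    comp_pool <- day_count - n_bump
    comp <- ifelse(comp_pool > 0, bump_sum / pmax(comp_pool, 1L), 0)
    take <- is_day & !in_dusk
    bump[take] <- bump[take] - comp[day_idx[take]]
  }

  # --- per-fish seasonal means --------------------------------------------
  meta <- synth_fish_metadata(cohort)
  warm_by_date <- month_by_date %in% cohort$warm_months

  set.seed(cohort$seed)
  phi <- exp(-1 / 60)                              # 1-h reversion at 1-min steps
  eps_sd <- cohort$depth_sd_within * sqrt(1 - phi^2)
  depth <- vector("list", nrow(meta))
  names(depth) <- meta$fish_id
  for (i in seq_len(nrow(meta))) {
    base_by_date <- ifelse(warm_by_date, meta$warm_mean[i], meta$cold_mean[i])
    x <- base_by_date[day_idx] + offset + bump
    if (cohort$depth_sd_within > 0) {
      noise <- as.numeric(stats::filter(rnorm(n_min, 0, eps_sd),
                                        phi, method = "recursive",
                                        init = rnorm(1, 0, cohort$depth_sd_within)))
      x <- x + noise
    }
    depth[[i]] <- pmin(pmax(x, 0), cohort$bottom_depth)
  }

  structure(list(start = start, n_min = n_min, depth = depth,
                 is_day = is_day, meta = meta, cohort = cohort),
            class = "fish_tracks")
}

tapply_sum <- function(x, g, nbins) {
  out <- numeric(nbins)
  nz <- x != 0
  if (any(nz)) {
    s <- rowsum(x[nz], g[nz])
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# Per-fish ground-truth metadata: archetypes, stratified DS cold means,
# dropout flags, and the descriptive fields a tagging sheet would carry.
synth_fish_metadata <- function(cohort) {
  n_keep <- cohort$n_ss + cohort$n_ds
  n_tot <- n_keep + cohort$dropout_fish
  archetype <- c(rep("SS", cohort$n_ss), rep("DS", cohort$n_ds),
                 rep(c("SS", "DS"), length.out = cohort$dropout_fish))
  # stratified grid of DS cold-period individual means, exactly centred on
  # the configured group mean with between-fish SD ds_cold_spread
  ds_cold <- cohort$ds_mean_depth_cold
  if (cohort$n_ds > 1L && cohort$ds_cold_spread > 0) {
    g <- seq_len(cohort$n_ds) - (cohort$n_ds + 1) / 2
    ds_cold <- cohort$ds_mean_depth_cold +
      g * cohort$ds_cold_spread / sqrt(mean(g^2))
  } else {
    ds_cold <- rep(cohort$ds_mean_depth_cold, cohort$n_ds)
  }
  cold_mean <- numeric(n_tot)
  warm_mean <- numeric(n_tot)
  is_ss <- archetype == "SS"
  cold_mean[is_ss] <- cohort$ss_mean_depth_cold
  warm_mean[is_ss] <- cohort$ss_mean_depth_warm
  cold_mean[which(!is_ss)[seq_len(cohort$n_ds)]] <- ds_cold
  # dropout DS fish (if any) sit at the group mean, keeping the grid exact
  cold_mean[!is_ss & cold_mean == 0] <- cohort$ds_mean_depth_cold
  warm_mean[!is_ss] <- cohort$ds_mean_depth_warm

  set.seed(cohort$seed + 7L)
  data.frame(
    fish_id = sprintf("F%02d", seq_len(n_tot)),
    archetype = archetype,
    cold_mean = cold_mean,
    warm_mean = warm_mean,
    dropout = c(rep(FALSE, n_keep), rep(TRUE, cohort$dropout_fish)),
    total_length = round(runif(n_tot, 31, 56)),
    capture_site = rep(c("TPA", "PPA"), length.out = n_tot),
    tagging_date = cohort$start_date,
    end_date = cohort$end_date,
    stringsAsFactors = FALSE
  )
}

#' Thin true tracks into an acoustic detection stream
#'
#' One candidate transmission per fish per nominal interval (midpoint of the
#' interval plus uniform jitter of +/- `jitter_frac` of the interval), each
#' retained independently with probability `detection_prob`. Fish flagged as
#' dropouts emit nothing after a uniform 3 to `dropout_max_days` day
#' post-release window. Receivers are assigned arbitrarily from the
#' configured list. The result is sorted by time.
#'
#' @param tracks A `"fish_tracks"` object from [simulate_true_tracks()].
#' @param cohort The [cohort_config()] used to build `tracks` (defaults to
#'   the one stored in `tracks`).
#'
#' @return A data.frame detection log: `timestamp` (POSIXct UTC),
#'   `transmitter_id`, `receiver_id`, `depth_m`.
#' @export
simulate_detections <- function(tracks, cohort = tracks$cohort) {
  stopifnot(inherits(tracks, "fish_tracks"))
  validate_cohort_config(cohort)
  total_s <- tracks$n_min * 60
  interval <- cohort$transmission_interval_s
  n_cand <- floor(total_s / interval)
  set.seed(cohort$seed + 1L)
  out <- vector("list", nrow(tracks$meta))
  for (i in seq_len(nrow(tracks$meta))) {
    t_s <- (seq_len(n_cand) - 0.5) * interval
    if (cohort$jitter_frac > 0)
      t_s <- t_s + runif(n_cand, -cohort$jitter_frac, cohort$jitter_frac) * interval
    t_s <- pmin(pmax(t_s, 0), total_s - 1)
    keep <- runif(n_cand) < cohort$detection_prob
    if (tracks$meta$dropout[i]) {
      window_s <- runif(1, 3, cohort$dropout_max_days) * 86400
      keep <- keep & t_s < window_s
    }
    t_s <- t_s[keep]
    if (!length(t_s)) next
    idx <- pmin(floor(t_s / 60) + 1, tracks$n_min)
    out[[i]] <- data.table(
      timestamp = tracks$start + t_s,
      transmitter_id = tracks$meta$fish_id[i],
      receiver_id = sample(cohort$receiver_ids, length(t_s), replace = TRUE),
      depth_m = round(tracks$depth[[i]][idx], 2)
    )
  }
  det <- data.table::rbindlist(out)
  if (nrow(det)) setorder(det, timestamp, transmitter_id)
  as.data.frame(det)
}

#' Simulate thermistor-string temperature profiles
#'
#' Surface temperature follows a seasonal sinusoid between
#' `surface_temp_min` and `surface_temp_max` peaking at `peak_doy`. In
#' `thermocline_months` the vertical profile is a logistic between the
#' surface temperature and `deep_temp`, whose mid-depth drifts smoothly from
#' the shallow to the deep end of `thermocline_depth_range` across the
#' season (plus a slow sinusoidal wander); in all other months the water
#' column is near-isothermal (weak linear lapse, total difference well under
#' the 3 degC thermocline gate). Independent Gaussian sensor noise is added.
#'
#' @param ocean An [ocean_config()].
#' @param times POSIXct vector (or dates) at which profiles are recorded.
#'
#' @return A long data.frame (`timestamp`, `depth_m`, `temp_c`); one row per
#'   sensor per time. The ground truth (`surface_temp`, `present`, `z_mid`
#'   per timestamp) is attached as attribute `"truth"`.
#' @export
simulate_thermistors <- function(ocean, times) {
  stopifnot(inherits(ocean, "ocean_config"))
  times <- as.POSIXct(times, tz = "UTC")
  lt <- as.POSIXlt(times, tz = "UTC")
  doy <- lt$yday + 1L
  mon <- lt$mon + 1L
  amp <- (ocean$surface_temp_max - ocean$surface_temp_min) / 2
  midT <- (ocean$surface_temp_max + ocean$surface_temp_min) / 2
  ts_surface <- midT + amp * cos(2 * pi * (doy - ocean$peak_doy) / 365)

  present <- mon %in% ocean$thermocline_months
  r <- ocean$thermocline_depth_range
  # seasonal drift of the mid-depth across the thermocline season
  ref_days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  in_season <- (as.POSIXlt(ref_days)$mon + 1L) %in% ocean$thermocline_months
  season_doy <- range(which(in_season))
  u <- (doy - season_doy[1]) / max(season_doy[2] - season_doy[1], 1L)
  u <- pmin(pmax(u, 0), 1)
  set.seed(ocean$seed)
  phase <- runif(1, 0, 2 * pi)
  z_mid <- (r[1] + 2) + u * ((r[2] - 2) - (r[1] + 2)) +
    2 * sin(2 * pi * doy / 45 + phase)
  z_mid <- pmin(pmax(z_mid, r[1]), r[2])
  z_mid[!present] <- NA_real_

  nz <- length(ocean$sensor_depths)
  n <- length(times)
  z <- rep(ocean$sensor_depths, times = n)
  ts_rep <- rep(ts_surface, each = nz)
  zm_rep <- rep(z_mid, each = nz)
  pr_rep <- rep(present, each = nz)
  temp <- ifelse(
    pr_rep,
    ocean$deep_temp + (ts_rep - ocean$deep_temp) /
      (1 + exp((z - zm_rep) / ocean$thermocline_sharpness)),
    ts_rep - ocean$isothermal_lapse * z
  )
  if (ocean$noise_sd > 0) temp <- temp + rnorm(length(temp), 0, ocean$noise_sd)

  out <- data.frame(
    timestamp = rep(times, each = nz),
    depth_m = z,
    temp_c = temp
  )
  attr(out, "truth") <- data.frame(
    timestamp = times, surface_temp = ts_surface,
    present = present, z_mid = z_mid
  )
  out
}

#' Simulate a full cohort: detections plus metadata
#'
#' Convenience wrapper chaining [simulate_true_tracks()] and
#' [simulate_detections()], returning the detection log together with the
#' tagging metadata (including the ground-truth archetype and dropout
#' columns used by tests).
#'
#' @param cohort A [cohort_config()].
#' @return A list with elements `detections` and `metadata`.
#' @export
simulate_cohort <- function(cohort) {
  tracks <- simulate_true_tracks(cohort)
  det <- simulate_detections(tracks, cohort)
  list(detections = det, metadata = tracks$meta)
}

#' Write generator outputs to CSV
#'
#' Detection logs are written with ISO-8601 UTC timestamps; metadata and
#' thermistor records with plain ISO dates/times.
#'
#' @param x A detection log, metadata data.frame, or thermistor data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(x, path) {
  x <- as.data.table(x)
  x[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(x, path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
write_metadata_csv <- function(x, path) {
  data.table::fwrite(as.data.table(x), path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
write_thermistors_csv <- function(x, path) {
  x <- as.data.table(x)
  x[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(x, path)
  invisible(path)
}
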