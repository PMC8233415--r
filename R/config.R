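#' Cohort configuration for the synthetic telemetry generator
#'
#' Defines the study conditions emulated by [simulate_true_tracks()] and
#' [simulate_detections()]: cohort composition (shallow-resident "SS" fish,
#' seasonally shifting "DS" fish, early dropouts), seasonal group mean depths,
#' the day/night depth offset, the dusk depth-excursion months, within-day
#' depth noise, and the acoustic transmission model.
#'
#' Defaults reproduce the structure of the brown meagre cohort the package is
#' designed around: 20 tagged fish of which 3 vanish days after release, an
#' SS group holding ~8 m year-round, a DS group moving from a stratified
#' 22.5 m cold-period group mean to 12 m in the warm months (April-August),
#' transmitters cycling every ~2 minutes, and a dusk activity peak in
#' June-July.
#'
#' @param n_ss,n_ds Number of shallow-resident (SS) and seasonally shifting
#'   (DS) fish that remain in the array for the whole study.
#' @param start_date,end_date Study window (`Date` or coercible).
#' @param site_lat,site_lon Site coordinates in decimal degrees (east/north
#'   positive).
#' @param ss_mean_depth_cold,ss_mean_depth_warm SS group mean depth (m) in
#'   cold and warm months.
#' @param ds_mean_depth_cold,ds_mean_depth_warm DS group mean depth (m) in
#'   cold and warm months. Individual DS cold-period means are spread on a
#'   symmetric grid around `ds_mean_depth_cold` (see `ds_cold_spread`).
#' @param ds_cold_spread Between-fish standard deviation (m) of the DS
#'   cold-period individual means; individuals sit on an evenly spaced grid
#'   with this SD, so the group mean is exactly `ds_mean_depth_cold`.
#' @param warm_months Integer months (1-12) in which the warm-period depths
#'   apply.
#' @param diel_amplitude_m Day-minus-night mean depth difference (m). The
#'   offset is weighted by the actual day/night duration of each date so the
#'   daily mean depth is unchanged.
#' @param dusk_peak_months Months in which an extra pre-sunset depth
#'   excursion is injected.
#' @param dusk_excursion_m Peak amplitude (m) of the dusk excursion.
#' @param depth_sd_within Stationary SD (m) of the within-day mean-reverting
#'   depth noise (1 h reversion timescale).
#' @param bottom_depth Sea-floor depth (m); simulated depths are clipped to
#'   `[0, bottom_depth]`.
#' @param transmission_interval_s Nominal transmitter cycle (s).
#' @param jitter_frac Uniform transmission-time jitter as a fraction of the
#'   interval (`0.1` = +/-10%).
#' @param detection_prob Probability that an emitted transmission is logged.
#' @param dropout_fish Number of additional fish that disappear within
#'   `dropout_max_days` of release.
#' @param dropout_max_days Upper bound (days) of the post-release window
#'   after which dropout fish stop emitting.
#' @param receiver_ids Character vector of receiver identifiers to assign
#'   arbitrarily to detections.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_ss = 8L,
                          n_ds = 9L,
                          start_date = as.Date("2016-06-01"),
                          end_date = as.Date("2018-06-01"),
                          site_lat = 42.48,
                          site_lon = 3.13,
                          ss_mean_depth_cold = 8.02,
                          ss_mean_depth_warm = 7.53,
                          ds_mean_depth_cold = 22.5,
                          ds_mean_depth_warm = 12,
                          ds_cold_spread = 4,
                          warm_months = 4:8,
                          diel_amplitude_m = 1.5,
                          dusk_peak_months = c(6L, 7L),
                          dusk_excursion_m = 6,
                          depth_sd_within = 1.5,
                          bottom_depth = 45,
                          transmission_interval_s = 120,
                          jitter_frac = 0.1,
                          detection_prob = 0.2,
                          dropout_fish = 3L,
                          dropout_max_days = 10,
                          receiver_ids = sprintf("R%02d", 1:17),
                          seed = 42L) {
  cfg <- list(
    n_ss = as.integer(n_ss), n_ds = as.integer(n_ds),
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    site_lat = site_lat, site_lon = site_lon,
    ss_mean_depth_cold = ss_mean_depth_cold,
    ss_mean_depth_warm = ss_mean_depth_warm,
    ds_mean_depth_cold = ds_mean_depth_cold,
    ds_mean_depth_warm = ds_mean_depth_warm,
    ds_cold_spread = ds_cold_spread,
    warm_months = as.integer(warm_months),
    diel_amplitude_m = diel_amplitude_m,
    dusk_peak_months = as.integer(dusk_peak_months),
    dusk_excursion_m = dusk_excursion_m,
    depth_sd_within = depth_sd_within,
    bottom_depth = bottom_depth,
    transmission_interval_s = transmission_interval_s,
    jitter_frac = jitter_frac,
    detection_prob = detection_prob,
    dropout_fish = as.integer(dropout_fish),
    dropout_max_days = dropout_max_days,
    receiver_ids = as.character(receiver_ids),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_ss + cfg$n_ds < 1L)
    stop("cohort must contain at least one fish (n_ss + n_ds >= 1)")
  if (cfg$start_date >= cfg$end_date)
    stop("start_date must precede end_date")
  depths <- c(cfg$ss_mean_depth_cold, cfg$ss_mean_depth_warm,
              cfg$ds_mean_depth_cold, cfg$ds_mean_depth_warm)
  if (any(depths < 0)) stop("configured mean depths must be >= 0")
  if (cfg$bottom_depth < max(depths))
    stop("bottom_depth is shallower than a configured mean depth")
  if (cfg$detection_prob < 0 || cfg$detection_prob > 1)
    stop("detection_prob must lie in [0, 1]")
  if (cfg$dropout_fish < 0L) stop("dropout_fish must be >= 0")
  if (!all(cfg$warm_months %in% 1:12)) stop("warm_months must be in 1..12")
  invisible(cfg)
}

#' Ocean / thermistor-string configuration for the synthetic generator
#'
#' Parameters of the simulated water column sampled by a fixed thermistor
#' string: a seasonal sinusoid for surface temperature, a constant deep
#' temperature, and a thermocline that exists only in `thermocline_months`,
#' whose mid-depth drifts smoothly across `thermocline_depth_range` over the
#' season. Defaults emulate the NW Mediterranean site the package targets:
#' 8 sensors at 5-40 m every 5 m, surface ~11.5 degC in late winter to
#' ~23 degC in August, and a June-November thermocline.
#'
#' @param surface_temp_min,surface_temp_max Seasonal extremes (degC) of the
#'   surface temperature sinusoid.
#' @param peak_doy Day of year at which surface temperature peaks.
#' @param deep_temp Temperature (degC) below the thermocline.
#' @param thermocline_months Integer months in which a thermocline exists.
#' @param thermocline_depth_range Length-2 numeric (m): the band within which
#'   the thermocline mid-depth drifts over the season. Must lie within the
#'   sensor span.
#' @param thermocline_sharpness Logistic scale parameter (m) of the vertical
#'   profile.
#' @param sensor_depths Thermistor depths (m), strictly increasing.
#' @param noise_sd Independent per-sensor measurement noise SD (degC).
#' @param isothermal_lapse Weak vertical gradient (degC per m) applied in
#'   non-thermocline months so mixed-season profiles are near- but not
#'   perfectly isothermal.
#' @param seed Integer seed.
#'
#' @return A list of class `"ocean_config"`.
#' @export
ocean_config <- function(surface_temp_min = 11.5,
                         surface_temp_max = 23,
                         peak_doy = 226L,
                         deep_temp = 12,
                         thermocline_months = 6:11,
                         thermocline_depth_range = c(8, 35),
                         thermocline_sharpness = 3,
                         sensor_depths = seq(5, 40, by = 5),
                         noise_sd = 0.1,
                         isothermal_lapse = 0.02,
                         seed = 42L) {
  cfg <- list(
    surface_temp_min = surface_temp_min,
    surface_temp_max = surface_temp_max,
    peak_doy = as.integer(peak_doy),
    deep_temp = deep_temp,
    thermocline_months = as.integer(thermocline_months),
    thermocline_depth_range = as.numeric(thermocline_depth_range),
    thermocline_sharpness = thermocline_sharpness,
    sensor_depths = as.numeric(sensor_depths),
    noise_sd = noise_sd,
    isothermal_lapse = isothermal_lapse,
    seed = as.integer(seed)
  )
  class(cfg) <- "ocean_config"
  if (!all(is.finite(c(cfg$surface_temp_min, cfg$surface_temp_max, cfg$deep_temp))))
    stop("temperatures must be finite")
  if (cfg$surface_temp_min > cfg$surface_temp_max)
    stop("surface_temp_min must not exceed surface_temp_max")
  if (length(cfg$thermocline_depth_range) != 2L ||
      diff(cfg$thermocline_depth_range) <= 0)
    stop("thermocline_depth_range must be an increasing length-2 range")
  if (is.unsorted(cfg$sensor_depths, strictly = TRUE))
    stop("sensor_depths must be strictly increasing")
  span <- range(cfg$sensor_depths)
  if (cfg$thermocline_depth_range[1] < span[1] ||
      cfg$thermocline_depth_range[2] > span[2])
    warning("thermocline_depth_range extends beyond the sensor span; ",
            "mid-depths outside the span cannot be recovered from the profiles")
  cfg
}

#' Read a cohort configuration from a YAML file
#'
#' Any field of [cohort_config()] may appear in the file; unspecified fields
#' keep their defaults. Dates are parsed with `as.Date()`.
#'
#' @param path Path to a YAML file.
#' @return A `"cohort_config"` list.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  do.call(cohort_config, vals)
}
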