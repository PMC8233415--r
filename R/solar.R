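#' Sunrise and sunset times from the NOAA solar-position equations
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 degrees, i.e.
#' including standard refraction and the solar disk radius) for one or more
#' calendar dates at a fixed site, using the NOAA general solar-position
#' calculations: the fractional-year Fourier expansions of the equation of
#' time and of solar declination, and the hour angle at the sunrise zenith.
#' Accuracy is a minute or two at mid-latitudes, which is ample for diel
#' labelling of hourly telemetry data.
#'
#' @param dates `Date` vector (civil dates at the site).
#' @param lat,lon Site latitude/longitude in decimal degrees (north/east
#'   positive). Latitudes poleward of the polar circles are rejected: no
#'   polar day/night handling is provided.
#'
#' @return A data.frame with columns `date`, `sunrise`, `sunset` (POSIXct,
#'   UTC) and `day_length_h`.
#' @export
#'
#' @examples
#' solar_events(as.Date("2017-06-21"), lat = 42.48, lon = 3.13)
solar_events <- function(dates, lat, lon) {
  dates <- as.Date(dates)
  if (abs(lat) >= 66.5)
    stop("latitudes poleward of the polar circles are unsupported")
  latr <- lat * pi / 180
  jd0 <- as.numeric(dates) + 2440587.5          # Julian day at 00:00 UTC
  event_minutes <- function(minutes_utc, rising) {
    sun <- noaa_sun(jd0 + minutes_utc / 1440)
    cos_ha <- cos(90.833 * pi / 180) / (cos(latr) * cos(sun$decl)) -
      tan(latr) * tan(sun$decl)
    if (any(abs(cos_ha) > 1))
      stop("sun does not rise or set on some requested dates at this latitude")
    ha <- acos(cos_ha) * 180 / pi   # degrees
    if (rising) 720 - 4 * (lon + ha) - sun$eqtime
    else 720 - 4 * (lon - ha) - sun$eqtime
  }
  # first pass at solar noon, then refine at the event time itself
  sunrise_min <- event_minutes(event_minutes(720, TRUE), TRUE)
  sunset_min <- event_minutes(event_minutes(720, FALSE), FALSE)
  midnight <- as.POSIXct(paste0(format(dates), " 00:00:00"), tz = "UTC")
  data.frame(
    date = dates,
    sunrise = midnight + sunrise_min * 60,
    sunset = midnight + sunset_min * 60,
    day_length_h = (sunset_min - sunrise_min) / 60
  )
}

# Solar declination (radians) and equation of time (minutes) at a Julian
# day, by the NOAA solar-calculator equations: Julian-century polynomial
# mean longitude and anomaly, equation of center, apparent ecliptic
# longitude with nutation term, corrected obliquity.
noaa_sun <- function(jd) {
  d2r <- pi / 180
  t <- (jd - 2451545) / 36525
  L0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  M <- (357.52911 + t * (35999.05029 - 0.0001537 * t)) * d2r
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  C <- sin(M) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * M) * (0.019993 - 0.000101 * t) + sin(3 * M) * 0.000289
  omega <- (125.04 - 1934.136 * t) * d2r
  lambda_app <- (L0 + C - 0.00569 - 0.00478 * sin(omega)) * d2r
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - 0.001813 * t))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos(omega)) * d2r
  decl <- asin(sin(eps) * sin(lambda_app))
  y <- tan(eps / 2)^2
  L0r <- L0 * d2r
  eqtime <- 4 / d2r * (y * sin(2 * L0r) - 2 * e * sin(M) +
    4 * e * y * sin(M) * cos(2 * L0r) -
    0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * M))
  list(decl = decl, eqtime = eqtime)
}

#' Label hourly depth records as day or night
#'
#' An hour bucket is labelled `"day"` when its midpoint (bucket start +
#' 30 min) falls within `[sunrise, sunset)` of its civil date at the site,
#' and `"night"` otherwise.
#'
#' @param hourly Hourly depth table from [hourly_mean_depth()] (needs
#'   `hour_start` POSIXct and `date_local` columns).
#' @param lat,lon Site coordinates (decimal degrees).
#'
#' @return `hourly` with a `diel_phase` factor column (levels `day`,
#'   `night`).
#' @export
label_diel <- function(hourly, lat, lon) {
  h <- as.data.table(hourly)
  ev <- solar_events(sort(unique(h$date_local)), lat, lon)
  ev <- as.data.table(ev)
  h <- ev[h, on = c(date = "date_local")]
  data.table::setnames(h, "date", "date_local")
  mid <- as.numeric(h$hour_start) + 1800
  h[, diel_phase := factor(ifelse(mid >= as.numeric(h$sunrise) &
                                    mid < as.numeric(h$sunset),
                                  "day", "night"),
                           levels = c("day", "night"))]
  h[, c("sunrise", "sunset", "day_length_h") := NULL]
  setorder(h, fish_id, hour_start)
  as.data.frame(h)
}
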