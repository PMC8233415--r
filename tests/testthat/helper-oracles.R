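# Independent oracles used across the test suite. These deliberately use
# different algorithms from the package implementations.

# --- solar ephemeris oracle -------------------------------------------------
# Low-precision Meeus-style solar position: Julian-day based mean longitude /
# anomaly, ecliptic longitude, declination and sidereal-time hour angle. The
# package uses the NOAA Fourier-series equations instead; the two share no
# code path or expansion.
oracle_sun_altitude <- function(time_utc, lat, lon) {
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 0.0000004 * n) * pi / 180
  delta <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  H <- (gmst_h * 15 + lon) * pi / 180 - ra
  phi <- lat * pi / 180
  asin(sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(H)) * 180 / pi
}

# Brute-force sunrise/sunset: scan the UTC day at 20 s resolution for
# crossings of altitude = -0.833 deg, refine linearly.
oracle_sun_events <- function(date, lat, lon) {
  t0 <- as.POSIXct(paste(format(as.Date(date)), "00:00:00"), tz = "UTC")
  ts <- t0 + seq(0, 86400, by = 20)
  alt <- oracle_sun_altitude(ts, lat, lon)
  f <- alt + 0.833
  cross <- which(f[-1] * f[-length(f)] < 0)
  refine <- function(i) {
    frac <- f[i] / (f[i] - f[i + 1])
    ts[i] + frac * 20
  }
  rising <- cross[f[cross] < 0]
  setting <- cross[f[cross] > 0]
  list(sunrise = if (length(rising)) refine(rising[1]) else NA,
       sunset = if (length(setting)) refine(setting[1]) else NA)
}

# --- exact 1-D 2-partition oracle -------------------------------------------
# Exhaustive search over all 2^n - 2 non-trivial assignments; returns the
# assignment (logical vector: TRUE = upper/shallow cluster) minimizing the
# within-cluster sum of squares.
oracle_two_partition <- function(x) {
  n <- length(x)
  best <- NULL
  best_wss <- Inf
  css <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  for (mask in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    wss <- css(x[a]) + css(x[!a])
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best <- a
    }
  }
  # orient so TRUE marks the cluster with the larger mean
  if (mean(x[best]) < mean(x[!best])) best <- !best
  best
}

# --- thermocline brute-force fitting oracle ---------------------------------
# Coarse grid search over the four logistic parameters, no derivatives, no
# Levenberg-Marquardt; adequate to localize the mid-depth to ~0.25 m.
oracle_logistic_fit <- function(depths, temps) {
  ts_grid <- seq(temps[1] - 1, temps[1] + 1, by = 0.2)
  td_grid <- seq(temps[length(temps)] - 1, temps[length(temps)] + 1, by = 0.2)
  zm_grid <- seq(min(depths), max(depths), by = 0.25)
  s_grid <- c(0.5, 1, 2, 3, 5, 8, 12)
  best <- list(rss = Inf)
  for (ts in ts_grid) for (td in td_grid) for (s in s_grid) {
    for (zm in zm_grid) {
      pred <- td + (ts - td) / (1 + exp((depths - zm) / s))
      rss <- sum((temps - pred)^2)
      if (rss < best$rss) best <- list(ts = ts, td = td, zm = zm, s = s, rss = rss)
    }
  }
  best
}
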