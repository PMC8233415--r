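#' Fit a four-parameter logistic to a vertical temperature profile
#'
#' Nonlinear least squares of
#' \deqn{T(z) = T_{deep} + \frac{T_{shallow} - T_{deep}}{1 + \exp((z - z_{mid})/s)}}
#' to one thermistor profile, with multi-start initialization
#' (surface/bottom sensors for the asymptotes, the steepest
#' finite-difference pair for `z_mid`, scale starts s in {1, 3, 10} m). The
#' fitted curve is evaluated on an 0.1 m grid spanning the sensor depths and
#' the thermocline mid-depth is the grid point of fastest temperature change
#' (argmax of the analytic |dT/dz|). The total temperature difference
#' `delta_t` is taken between the shallowest and deepest sensors (the
#' "surface" proxy and the deepest measure); a thermocline is declared
#' `present` only when `delta_t` exceeds 3 degC, and `mid_depth` is `NA`
#' otherwise.
#'
#' @param depths Sensor depths (m), strictly increasing, at least 4.
#' @param temps Temperatures (degC) at those depths.
#' @param gate_degc Presence gate on the surface-to-deep temperature
#'   difference (degC).
#' @param grid_step Evaluation grid step (m).
#'
#' @return A list of class `"thermocline_estimate"`: `params` (named:
#'   `t_shallow`, `t_deep`, `z_mid`, `s`), `mid_depth`, `delta_t`,
#'   `present`, `fit_rss`, `converged`, plus the input `depths`/`temps`.
#' @export
fit_profile <- function(depths, temps, gate_degc = 3, grid_step = 0.1) {
  stopifnot(length(depths) == length(temps))
  if (length(depths) < 4L) stop("a profile needs at least 4 sensors")
  if (is.unsorted(depths, strictly = TRUE))
    stop("sensor depths must be strictly increasing")
  delta_t <- abs(temps[1L] - temps[length(temps)])
  present <- isTRUE(delta_t > gate_degc)

  fit <- fit_logistic_profile(depths, temps)
  mid_depth <- NA_real_
  if (present && fit$converged) {
    grid <- seq(min(depths), max(depths), by = grid_step)
    if (grid[length(grid)] < max(depths)) grid <- c(grid, max(depths))
    p <- fit$params
    e <- exp((grid - p[["z_mid"]]) / p[["s"]])
    dT <- abs((p[["t_shallow"]] - p[["t_deep"]]) * e / (p[["s"]] * (1 + e)^2))
    mid_depth <- grid[which.max(dT)]
  }
  structure(list(params = fit$params, mid_depth = mid_depth,
                 delta_t = delta_t, present = present,
                 fit_rss = fit$rss, converged = fit$converged,
                 depths = depths, temps = temps),
            class = "thermocline_estimate")
}

# multi-start Levenberg-Marquardt fit of the 4-parameter logistic
fit_logistic_profile <- function(depths, temps) {
  dd <- diff(temps) / diff(depths)
  z_steep <- (depths[which.max(abs(dd))] + depths[which.max(abs(dd)) + 1L]) / 2
  span <- range(depths)
  best <- NULL
  df <- data.frame(z = depths, y = temps)
  for (s0 in c(1, 3, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ td + (ts - td) / (1 + exp((z - zm) / s)),
        data = df,
        start = list(ts = temps[1L], td = temps[length(temps)],
                     zm = z_steep, s = s0),
        lower = c(ts = -5, td = -5, zm = span[1], s = 0.1),
        upper = c(ts = 40, td = 40, zm = span[2], s = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-8) {
      cf <- coef(fit)
      best <- list(params = c(t_shallow = unname(cf["ts"]),
                              t_deep = unname(cf["td"]),
                              z_mid = unname(cf["zm"]),
                              s = unname(cf["s"])),
                   rss = rss, converged = TRUE)
    }
  }
  if (is.null(best))
    best <- list(params = c(t_shallow = NA_real_, t_deep = NA_real_,
                            z_mid = NA_real_, s = NA_real_),
                 rss = NA_real_, converged = FALSE)
  best
}

#' @export
print.thermocline_estimate <- function(x, ...) {
  cat("Thermocline estimate: ",
      if (x$present) sprintf("present, mid-depth %.1f m", x$mid_depth)
      else "absent",
      sprintf(" (delta T = %.2f degC", x$delta_t),
      if (x$converged) sprintf(", RSS = %.3g)", x$fit_rss) else ", fit failed)",
      "\n", sep = "")
  invisible(x)
}

#' Thermocline estimates for a stream of profiles
#'
#' Fits [fit_profile()] to every distinct timestamp of a long thermistor
#' table and returns one row per profile. Profiles whose fit fails to
#' converge are flagged (`converged = FALSE`) and carry no mid-depth.
#'
#' @param profiles Long data.frame with `timestamp`, `depth_m`, `temp_c`.
#' @inheritParams fit_profile
#' @return A data.frame: `timestamp`, `present`, `mid_depth`, `delta_t`,
#'   `fit_rss`, `converged`.
#' @export
thermocline_series <- function(profiles, gate_degc = 3, grid_step = 0.1) {
  pr <- as.data.table(profiles)
  if (!nrow(pr))
    return(data.frame(timestamp = as.POSIXct(character()),
                      present = logical(), mid_depth = numeric(),
                      delta_t = numeric(), fit_rss = numeric(),
                      converged = logical()))
  setorder(pr, timestamp, depth_m)
  res <- pr[, {
    est <- fit_profile(depth_m, temp_c, gate_degc = gate_degc,
                       grid_step = grid_step)
    .(present = est$present, mid_depth = est$mid_depth,
      delta_t = est$delta_t, fit_rss = est$fit_rss,
      converged = est$converged)
  }, by = timestamp]
  n_bad <- sum(!res$converged)
  if (n_bad) message(n_bad, " profile fit(s) did not converge and are flagged")
  as.data.frame(res)
}

#' Daily mean thermocline mid-depth
#'
#' Mean of the present (and converged) mid-depths per civil date.
#'
#' @param series Output of [thermocline_series()].
#' @param tz Time zone for daily binning.
#' @return A data.frame `date`, `mid_depth`, `n_profiles`.
#' @export
daily_thermocline <- function(series, tz = "Europe/Paris") {
  s <- as.data.table(series)[present & converged & !is.na(mid_depth)]
  if (!nrow(s))
    return(data.frame(date = as.Date(character()), mid_depth = numeric(),
                      n_profiles = integer()))
  s[, date := as.Date(format(timestamp, "%Y-%m-%d", tz = tz))]
  out <- s[, .(mid_depth = mean(mid_depth), n_profiles = .N), by = date]
  setorder(out, date)
  as.data.frame(out)
}

#' Temperature at a given depth from a fitted profile
#'
#' Evaluates the fitted logistic when the fit converged, and falls back to
#' linear interpolation between the bracketing sensors otherwise. Depths
#' outside the sensor span are an error.
#'
#' @param estimate A `"thermocline_estimate"` from [fit_profile()].
#' @param z Depth (m), within the sensor span.
#' @return Temperature in degC.
#' @export
temp_at_depth <- function(estimate, z) {
  stopifnot(inherits(estimate, "thermocline_estimate"))
  span <- range(estimate$depths)
  if (any(z < span[1] | z > span[2]))
    stop("depth outside the sensor span [", span[1], ", ", span[2], "] m")
  if (estimate$converged) {
    p <- estimate$params
    p[["t_deep"]] + (p[["t_shallow"]] - p[["t_deep"]]) /
      (1 + exp((z - p[["z_mid"]]) / p[["s"]]))
  } else {
    approx(estimate$depths, estimate$temps, xout = z)$y
  }
}
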