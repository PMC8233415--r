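#' Standardize fish depth to Z-scores
#'
#' Standardizes hourly depth to zero mean and unit variance over all
#' fish-hours jointly. Under the default `"elevation"` orientation the
#' standardized variable is the signed elevation (minus depth), so positive
#' Z-scores mean *shallower* than the population average -- the convention
#' under which the warm period is the set of months with positive mean
#' Z-scores. The `"depth"` orientation standardizes depth itself (sign
#' flipped).
#'
#' @param hourly Hourly depth table ([hourly_mean_depth()] output or
#'   anything with `fish_id` and `mean_depth`).
#' @param orientation `"elevation"` (default; positive Z = shallow) or
#'   `"depth"`.
#' @return `hourly` with a `z` column; the standardization constants are
#'   attached as attributes `global_mean` and `global_sd` (on the oriented
#'   scale).
#' @export
standardize_depth <- function(hourly, orientation = c("elevation", "depth")) {
  orientation <- match.arg(orientation)
  h <- as.data.table(hourly)
  if (nrow(h) < 2L) stop("at least two fish-hours are required")
  x <- if (orientation == "elevation") -h$mean_depth else h$mean_depth
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("depth has zero variance; Z-scores are undefined")
  h[, z := (x - m) / s]
  out <- as.data.frame(h)
  attr(out, "global_mean") <- m
  attr(out, "global_sd") <- s
  attr(out, "orientation") <- orientation
  out
}

#' Exact two-group split of per-fish mean Z-scores
#'
#' One-dimensional two-means clustering solved exactly: every cut point of
#' the sorted per-fish means is scanned and the partition minimizing the
#' within-cluster sum of squares is returned (for one dimension the optimal
#' two-means partition is always an interval split, so the scan is exact and
#' deterministic). The cluster with the larger mean Z -- the shallower fish
#' under the elevation orientation -- is labelled `SS`, the other `DS`.
#'
#' @param fish_mean_z Named numeric vector of per-fish mean Z-scores.
#' @return A factor (levels `DS`, `SS`) named by fish.
#' @export
cluster_groups <- function(fish_mean_z) {
  if (length(fish_mean_z) < 2L) stop("need at least two fish to split")
  if (is.null(names(fish_mean_z)))
    names(fish_mean_z) <- as.character(seq_along(fish_mean_z))
  if (diff(range(fish_mean_z)) == 0)
    stop("all per-fish mean Z-scores identical; no two-group split exists")
  ord <- order(fish_mean_z)
  xs <- fish_mean_z[ord]
  n <- length(xs)
  css <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  wss <- vapply(seq_len(n - 1L),
                function(k) css(xs[1:k]) + css(xs[(k + 1L):n]),
                numeric(1))
  k <- which.min(wss)
  lab <- rep("DS", n)
  lab[(k + 1L):n] <- "SS"           # upper (shallower) cluster
  out <- factor(lab, levels = c("DS", "SS"))
  names(out) <- names(xs)
  out[match(names(fish_mean_z), names(out))]
}

#' Classify warm and cold months from DS monthly Z-scores
#'
#' A month (pooled across calendar years) belongs to the warm period when at
#' least `min_fish` DS-group fish have a strictly positive mean Z-score that
#' month; all other months are cold. No contiguity of the warm set is
#' enforced.
#'
#' @param monthly_mean_z Data.frame with `fish_id`, `month` (1-12) and
#'   `mean_z`.
#' @param groups Factor from [cluster_groups()], named by fish.
#' @param min_fish Minimum number of positive-Z DS fish (default 3).
#' @return Sorted integer vector of warm months.
#' @export
classify_periods <- function(monthly_mean_z, groups, min_fish = 3L) {
  mz <- as.data.table(monthly_mean_z)
  ds_fish <- names(groups)[groups == "DS"]
  if (!length(ds_fish)) stop("no DS fish; the period rule is undefined")
  mz <- mz[fish_id %in% ds_fish]
  pos <- mz[mean_z > 0, .(n_pos = data.table::uniqueN(fish_id)), by = month]
  sort(pos[n_pos >= min_fish, month])
}

#' Segment a cohort: Z-scores, SS/DS groups, warm/cold months
#'
#' Runs the whole segmentation stage on an hourly depth table:
#' standardization over all fish-hours, per-fish total and monthly mean
#' Z-scores, the exact two-means SS/DS split, and the warm-month rule.
#' The returned hourly table gains `z`, `group` and `period` columns.
#'
#' @inheritParams standardize_depth
#' @param min_fish Minimum positive-Z DS fish for a warm month.
#' @return A list of class `"bathyseg_segmentation"`: `hourly`,
#'   `fish_mean_z`, `monthly_mean_z`, `groups`, `warm_months`,
#'   `global_mean`, `global_sd`.
#' @export
segment_cohort <- function(hourly, orientation = c("elevation", "depth"),
                           min_fish = 3L) {
  hz <- standardize_depth(hourly, orientation)
  h <- as.data.table(hz)
  fish_mean_z <- h[, .(mean_z = mean(z)), by = fish_id]
  fmz <- setNames(fish_mean_z$mean_z, fish_mean_z$fish_id)
  groups <- cluster_groups(fmz)
  monthly <- as.data.frame(h[, .(mean_z = mean(z)), by = .(fish_id, month)])
  warm <- classify_periods(monthly, groups, min_fish = min_fish)
  h[, group := groups[fish_id]]
  h[, period := factor(ifelse(month %in% warm, "warm", "cold"),
                       levels = c("cold", "warm"))]
  structure(list(hourly = as.data.frame(h), fish_mean_z = fmz,
                 monthly_mean_z = monthly, groups = groups,
                 warm_months = warm,
                 global_mean = attr(hz, "global_mean"),
                 global_sd = attr(hz, "global_sd")),
            class = "bathyseg_segmentation")
}

#' @export
print.bathyseg_segmentation <- function(x, ...) {
  cat("Cohort segmentation\n")
  cat("  fish:", length(x$groups), " (SS ", sum(x$groups == "SS"),
      " / DS ", sum(x$groups == "DS"), ")\n", sep = "")
  cat("  warm months:", paste(month.abb[x$warm_months], collapse = ", "), "\n")
  invisible(x)
}

#' Mean depth by group and period
#'
#' Arithmetic mean and standard error of the hourly mean depths per
#' (group, period) cell, plus per-fish monthly means for stratification
#' displays. Empty cells are absent (with a warning when a group/period
#' combination is missing entirely).
#'
#' @param hourly Hourly table carrying `group` and `period` columns (e.g.
#'   `segment_cohort(...)$hourly`).
#' @return A list: `by_group_period` (`group`, `period`, `mean_depth`, `se`,
#'   `n`) and `fish_monthly` (`fish_id`, `group`, `month`, `mean_depth`,
#'   `se`, `n`).
#' @export
period_depth_summary <- function(hourly) {
  h <- as.data.table(hourly)
  stopifnot(all(c("group", "period", "mean_depth") %in% names(h)))
  gp <- h[, .(mean_depth = mean(mean_depth),
              se = sd(mean_depth) / sqrt(.N), n = .N),
          by = .(group, period)]
  setorder(gp, group, period)
  full <- data.table::CJ(group = levels(h$group), period = levels(h$period))
  if (nrow(gp) < nrow(full))
    warning("empty group x period cell(s) omitted from the summary")
  fm <- h[, .(mean_depth = mean(mean_depth),
              se = sd(mean_depth) / sqrt(.N), n = .N),
          by = .(fish_id, group, month)]
  setorder(fm, fish_id, month)
  list(by_group_period = as.data.frame(gp), fish_monthly = as.data.frame(fm))
}
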