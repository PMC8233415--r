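#' Day/night depth variance as a vertical-activity proxy
#'
#' Sample variance (denominator n-1) of the hourly mean depths within each
#' (fish, date, diel phase) cell. A larger variance is read as a wider range
#' of vertical movement, hence higher activity. Cells with fewer than
#' `min_hours` hourly values are dropped (a message reports how many), so
#' every retained variance has at least `min_hours - 1` degrees of freedom.
#'
#' @param hourly Hourly table with diel labels (`fish_id`, `date_local`,
#'   `diel_phase`, `mean_depth`; `month`, `period`, `group` are carried
#'   through when present).
#' @param min_hours Minimum hourly values per cell (default 3).
#' @return A data.frame: `fish_id`, `date_local`, `diel_phase`,
#'   `depth_variance`, `n_hours`, plus `month`/`period`/`group` if present.
#' @export
diel_variance <- function(hourly, min_hours = 3L) {
  h <- as.data.table(hourly)
  stopifnot(all(c("fish_id", "date_local", "diel_phase", "mean_depth")
                %in% names(h)))
  carry <- intersect(c("month", "period", "group"), names(h))
  rec <- h[, c(.(depth_variance = var(mean_depth), n_hours = .N),
               lapply(.SD, data.table::first)),
           by = .(fish_id, date_local, diel_phase), .SDcols = carry]
  n_drop <- sum(rec$n_hours < min_hours)
  if (n_drop) message(n_drop, " cell(s) below the ", min_hours,
                      "-hour support threshold dropped")
  rec <- rec[n_hours >= min_hours]
  setorder(rec, fish_id, date_local, diel_phase)
  as.data.frame(rec)
}

#' Monthly mean log-activity by group and diel phase
#'
#' Mean and standard error of the log-transformed activity proxy,
#' `ln(variance + 1)`, per (group, diel phase, month) cell, months pooled
#' across calendar years. Empty cells are absent.
#'
#' @param records Activity records from [diel_variance()]; must carry
#'   `group` and `month` columns.
#' @return A data.frame: `group`, `diel_phase`, `month`, `mean_log_activity`,
#'   `se`, `n`.
#' @export
monthly_activity <- function(records) {
  r <- as.data.table(records)
  stopifnot(all(c("group", "diel_phase", "month", "depth_variance")
                %in% names(r)))
  r[, log_act := log1p(depth_variance)]
  out <- r[, .(mean_log_activity = mean(log_act),
               se = sd(log_act) / sqrt(.N), n = .N),
           by = .(group, diel_phase, month)]
  setorder(out, group, diel_phase, month)
  as.data.frame(out)
}
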