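#' Read an acoustic detection log
#'
#' Expects a CSV with columns `timestamp` (ISO-8601, UTC), `transmitter_id`,
#' `receiver_id` and `depth_m`. Rows with unparseable timestamps are skipped
#' with a warning giving their line numbers; exact duplicates of
#' (transmitter, timestamp, receiver) are dropped with a message. Records
#' are returned sorted by fish and time.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `fish_id`, `timestamp` (POSIXct UTC),
#'   `receiver_id`, `depth`.
#' @export
read_detections <- function(path) {
  raw <- data.table::fread(path, colClasses = list(character = "timestamp"))
  need <- c("timestamp", "transmitter_id", "receiver_id", "depth_m")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("detection file is missing required column(s): ",
         paste(miss, collapse = ", "))
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], f, tz = "UTC"))
  }
  bad <- which(is.na(ts) & !is.na(raw$timestamp) & nzchar(raw$timestamp))
  if (length(bad))
    warning(length(bad), " row(s) with unparseable timestamps skipped (lines ",
            paste(head(bad + 1L, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "", ")")
  det <- data.table(
    fish_id = as.character(raw$transmitter_id),
    timestamp = ts,
    receiver_id = as.character(raw$receiver_id),
    depth = as.numeric(raw$depth_m)
  )[!is.na(ts)]
  n0 <- nrow(det)
  det <- unique(det, by = c("fish_id", "timestamp", "receiver_id"))
  if (nrow(det) < n0)
    message(n0 - nrow(det), " duplicate detection(s) dropped")
  setorder(det, fish_id, timestamp)
  as.data.frame(det)
}

#' Hourly mean depth per fish
#'
#' Arithmetic mean of detection depths per fish and clock hour. Hours are
#' civil hours at the site (`tz`, default Central European time with DST),
#' matching the local sunrise/sunset frame used for diel labelling; hours
#' with no detections are simply absent.
#'
#' @param detections Detection data.frame (`fish_id`, `timestamp`, `depth`).
#' @param tz Olson time zone of the site.
#' @return A data.frame with `fish_id`, `date_local` (Date), `hour` (0-23),
#'   `hour_start` (POSIXct), `month`, `mean_depth`, `n_detections`.
#' @export
hourly_mean_depth <- function(detections, tz = "Europe/Paris") {
  det <- as.data.table(detections)
  if (!nrow(det))
    return(data.frame(fish_id = character(), date_local = as.Date(character()),
                      hour = integer(), hour_start = as.POSIXct(character()),
                      month = integer(), mean_depth = numeric(),
                      n_detections = integer()))
  lt <- as.POSIXlt(det$timestamp, tz = tz)
  det[, `:=`(date_local = as.Date(format(timestamp, "%Y-%m-%d", tz = tz)),
             hour = lt$hour)]
  h <- det[, .(mean_depth = mean(depth), n_detections = .N),
           by = .(fish_id, date_local, hour)]
  h[, month := as.POSIXlt(date_local)$mon + 1L]
  h[, hour_start := as.POSIXct(paste0(format(date_local), " ",
                                      sprintf("%02d", hour), ":00:00"),
                               tz = tz)]
  setorder(h, fish_id, hour_start)
  as.data.frame(h[, .(fish_id, date_local, hour, hour_start, month,
                      mean_depth, n_detections)])
}

# round-half-up, used for all reported summary columns
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Residence and detection summary per fish
#'
#' For every fish in the metadata: the tracking period in whole days
#' (metadata end date minus tagging date), the number of distinct civil
#' dates with at least one detection, the residence index (days detected /
#' tracking period; reported rounded to 2 decimals, half-up), total
#' detections, and detections per day (total / tracking period, rounded
#' half-up to an integer). Detections after the metadata end date are
#' discarded with a warning; fish present in the log but absent from the
#' metadata are an error.
#'
#' @param detections Detection data.frame (`fish_id`, `timestamp`, `depth`).
#' @param metadata Data.frame with `fish_id`, `tagging_date`, `end_date`
#'   (and optionally `total_length`, `capture_site`).
#' @param tz Olson time zone used for daily binning.
#' @return A data.frame, one row per metadata fish, with columns
#'   `fish_id`, `tracking_period`, `days_detected`, `residence_index`,
#'   `total_detections`, `detections_per_day`, `last_detected` plus any
#'   descriptive metadata columns.
#' @export
residence_summary <- function(detections, metadata, tz = "Europe/Paris") {
  det <- as.data.table(detections)
  meta <- as.data.table(metadata)
  stopifnot(all(c("fish_id", "tagging_date", "end_date") %in% names(meta)))
  meta[, `:=`(tagging_date = as.Date(tagging_date),
              end_date = as.Date(end_date))]
  orphan <- setdiff(unique(det$fish_id), meta$fish_id)
  if (length(orphan))
    stop("fish present in the detection log but not in the metadata: ",
         paste(orphan, collapse = ", "))
  if (nrow(det)) {
    det[, date_local := as.Date(format(timestamp, "%Y-%m-%d", tz = tz))]
    det <- meta[, .(fish_id, end_date)][det, on = "fish_id"]
    late <- det$date_local >= det$end_date
    if (any(late)) {
      warning(sum(late), " detection(s) on/after the metadata end date discarded")
      det <- det[!late]
    }
    per_fish <- det[, .(days_detected = data.table::uniqueN(date_local),
                        total_detections = .N,
                        last_detected = max(date_local)),
                    by = fish_id]
  } else {
    per_fish <- data.table(fish_id = character(), days_detected = integer(),
                           total_detections = integer(),
                           last_detected = as.Date(character()))
  }
  out <- per_fish[meta, on = "fish_id"]
  out[is.na(days_detected), `:=`(days_detected = 0L, total_detections = 0L)]
  out[, tracking_period := as.integer(end_date - tagging_date)]
  out[, residence_index := round_half_up(days_detected / tracking_period, 2)]
  out[, detections_per_day := as.integer(
    round_half_up(total_detections / tracking_period))]
  first <- c("fish_id", "tracking_period", "days_detected", "residence_index",
             "total_detections", "detections_per_day", "last_detected")
  data.table::setcolorder(out, c(first, setdiff(names(out), first)))
  as.data.frame(out)
}

#' Flag fish that left the array shortly after release
#'
#' A fish is excluded when its last detection falls fewer than
#' `min_span_days` days after tagging (fish never detected are excluded for
#' any positive `min_span_days`). Supplying `exclude_ids` overrides the rule
#' entirely: exactly those fish are excluded.
#'
#' @param fish_records Output of [residence_summary()].
#' @param min_span_days Minimum detection span (days) for inclusion.
#' @param exclude_ids Optional character vector of fish to exclude instead
#'   of applying the span rule.
#' @return `fish_records` with a logical `included` column.
#' @export
exclude_dropouts <- function(fish_records, min_span_days = 30,
                             exclude_ids = NULL) {
  fr <- as.data.table(fish_records)
  if (!is.null(exclude_ids)) {
    fr[, included := !fish_id %in% as.character(exclude_ids)]
  } else {
    span <- as.numeric(fr$last_detected - as.Date(fr$tagging_date))
    span[is.na(span)] <- -Inf
    fr[, included := span >= min_span_days | min_span_days <= 0]
  }
  as.data.frame(fr)
}

#' Tagged-fish summary table packaged with bathyseg
#'
#' Loads the packaged transcription of the study's tagged-fish summary (20
#' brown meagre at two capture sites) and recomputes the derived columns
#' (residence index, detections per day) from the raw counts. The
#' `included` flag marks the 17 analyzed fish; the three excluded
#' individuals disappeared from the array days after release.
#'
#' @return A data.frame, one row per tagged fish.
#' @export
fish_summary_fixture <- function() {
  path <- system.file("extdata", "table1_fish_summary.csv",
                      package = "bathyseg", mustWork = TRUE)
  x <- as.data.table(data.table::fread(path))
  x[, tagging_date := as.Date(tagging_date, format = "%d/%m/%Y")]
  x[, residence_index := round_half_up(days_detected / tracking_period, 2)]
  x[, detections_per_day := as.integer(
    round_half_up(total_detections / tracking_period))]
  x[, included := !excluded]
  as.data.frame(x)
}
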