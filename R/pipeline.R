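#' Run the depth-distribution pipeline on a detection log
#'
#' Chains the processing stages on raw inputs: residence summary and dropout
#' exclusion, hourly averaging, diel labelling, Z-score segmentation into
#' SS/DS groups and warm/cold months, and the group x period depth summary.
#'
#' @param detections Detection data.frame (`fish_id`, `timestamp`, `depth`),
#'   or a raw log with `transmitter_id`/`depth_m` columns as produced by
#'   [simulate_detections()] (renamed automatically).
#' @param metadata Fish metadata (`fish_id`, `tagging_date`, `end_date`).
#' @param lat,lon Site coordinates.
#' @param tz Site civil time zone.
#' @param min_span_days Dropout-exclusion threshold (days).
#' @param exclude_ids Optional explicit exclusion list overriding the rule.
#' @param min_fish Minimum positive-Z DS fish for a warm month.
#'
#' @return A list: `fish_summary` (with `included`), `hourly` (included fish,
#'   with `diel_phase`, `z`, `group`, `period`), `segmentation`
#'   ([segment_cohort()] result) and `period_summary`
#'   ([period_depth_summary()] result).
#' @export
run_depth_pipeline <- function(detections, metadata,
                               lat = 42.48, lon = 3.13, tz = "Europe/Paris",
                               min_span_days = 30, exclude_ids = NULL,
                               min_fish = 3L) {
  det <- as.data.frame(detections)
  if (!"fish_id" %in% names(det) && "transmitter_id" %in% names(det))
    names(det)[names(det) == "transmitter_id"] <- "fish_id"
  if (!"depth" %in% names(det) && "depth_m" %in% names(det))
    names(det)[names(det) == "depth_m"] <- "depth"
  fs <- residence_summary(det, metadata, tz = tz)
  fs <- exclude_dropouts(fs, min_span_days = min_span_days,
                         exclude_ids = exclude_ids)
  keep <- fs$fish_id[fs$included]
  det <- det[det$fish_id %in% keep, , drop = FALSE]
  hourly <- hourly_mean_depth(det, tz = tz)
  hourly <- label_diel(hourly, lat, lon)
  seg <- segment_cohort(hourly, min_fish = min_fish)
  list(fish_summary = fs, hourly = seg$hourly, segmentation = seg,
       period_summary = period_depth_summary(seg$hourly))
}
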