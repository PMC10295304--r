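# Per-recording comparison of camera-based RR against the EDR reference and
# study-level summaries: relative / absolute error per recording, unweighted
# means over recordings, and range / SD of the reference column.

#' Compare one recording's camera RR against its EDR reference
#'
#' @param mean_edr Mean EDR rate over the recording, breaths/min (> 0).
#' @param mean_cam Mean camera-based RR, breaths/min.
#' @param day,mt,rat_id Optional recording labels (measurement day, time
#'   point, animal id).
#' @return A `recording_comparison` data frame row with
#'   `rel_error = 100 * |mean_cam - mean_edr| / mean_edr` (percent) and
#'   `abs_error = |mean_cam - mean_edr|` (breaths/min), kept at full
#'   precision (round only for presentation).
#' @export
compare_recording <- function(mean_edr, mean_cam, day = "", mt = "",
                              rat_id = "") {
  if (any(mean_edr <= 0)) stop("reference rate must be positive")
  out <- data.frame(day = day, mt = mt, rat_id = rat_id,
                    mean_edr = mean_edr, mean_cam = mean_cam,
                    rel_error = 100 * abs(mean_cam - mean_edr) / mean_edr,
                    abs_error = abs(mean_cam - mean_edr))
  class(out) <- c("recording_comparison", "data.frame")
  out
}

#' Summarize a study of recording comparisons
#'
#' Unweighted arithmetic means over recordings of the reference rate, the
#' camera rate and both errors, plus min / max / sample SD of the reference
#' column.
#'
#' @param rows A data frame of [compare_recording()] rows (columns
#'   `mean_edr`, `mean_cam`, `rel_error`, `abs_error`).
#' @return A `study_summary` list.
#' @export
summarize_study <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  need <- c("mean_edr", "mean_cam", "rel_error", "abs_error")
  if (!all(need %in% names(rows)))
    stop("rows must contain columns: ", paste(need, collapse = ", "))
  structure(list(
    n_recordings = nrow(rows),
    mean_edr_overall = mean(rows$mean_edr),
    mean_cam_overall = mean(rows$mean_cam),
    mean_rel_error = mean(rows$rel_error),
    mean_abs_error = mean(rows$abs_error),
    edr_min = min(rows$mean_edr),
    edr_max = max(rows$mean_edr),
    edr_sd = if (nrow(rows) > 1L) stats::sd(rows$mean_edr) else NA_real_
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<study_summary> %d recordings\n",
           "  reference RR: mean %.2f (range %.2f-%.2f, SD %.2f) breaths/min\n",
           "  camera RR:    mean %.2f breaths/min\n",
           "  error: rel %.2f%%, abs %.2f breaths/min\n"),
    x$n_recordings, x$mean_edr_overall, x$edr_min, x$edr_max, x$edr_sd,
    x$mean_cam_overall, x$mean_rel_error, x$mean_abs_error))
  invisible(x)
}

#' Build the per-recording comparison table from two mean-RR tables
#'
#' Joins camera and reference per-recording means on `(day, mt, rat_id)` and
#' computes the error columns.
#'
#' @param cam Data frame with `day`, `mt`, `rat_id`, `mean_rr` (camera).
#' @param edr Data frame with `day`, `mt`, `rat_id`, `mean_rr` (reference).
#' @return A `recording_comparison` data frame, one row per matched
#'   recording.
#' @export
evaluate_recordings <- function(cam, edr) {
  key <- c("day", "mt", "rat_id")
  stopifnot(all(key %in% names(cam)), all(key %in% names(edr)),
            "mean_rr" %in% names(cam), "mean_rr" %in% names(edr))
  m <- merge(edr, cam, by = key, suffixes = c("_edr", "_cam"))
  if (nrow(m) == 0L) stop("no recordings match on (day, mt, rat_id)")
  compare_recording(m$mean_rr_edr, m$mean_rr_cam,
                    day = m$day, mt = m$mt, rat_id = m$rat_id)
}

#' Round a comparison table for presentation (2 decimals, half-even)
#'
#' @param rows A `recording_comparison` data frame.
#' @return The table with numeric columns rounded to 2 decimals.
#' @export
format_comparison <- function(rows) {
  for (col in c("mean_edr", "mean_cam", "rel_error", "abs_error"))
    rows[[col]] <- round(rows[[col]], 2)
  rows
}

#' Bundled reference table: per-recording mean respiratory rates
#'
#' Per-recording mean EDR and camera RR (breaths/min) with their printed
#' relative and absolute errors from a three-rat telemetry-validated
#' monitoring study (36 five-minute recordings over four days). Shipped so
#' the evaluation arithmetic can be exercised and cross-checked without any
#' raw recordings.
#'
#' @return A data frame with columns `day`, `mt`, `rat_id`, `mean_edr`,
#'   `mean_cam`, `rel_error`, `abs_error`.
#' @export
reference_rr_recordings <- function() {
  utils::read.csv(system.file("extdata", "rr_recordings.csv",
                              package = "ratresp"),
                  stringsAsFactors = FALSE)
}

#' Bundled reference table: per-animal segmentation IoU summaries
#'
#' Per-animal counts and mean +/- SD of bounding-box IoU, mask IoU and
#' segmenter certainty score (percent) from the same study's
#' cross-validated segmentation evaluation.
#'
#' @return A data frame with columns `rat_id`, `n`, `iou_box_mean`,
#'   `iou_box_sd`, `iou_mask_mean`, `iou_mask_sd`, `certainty_mean`,
#'   `certainty_sd`.
#' @export
reference_iou_by_rat <- function() {
  utils::read.csv(system.file("extdata", "iou_by_rat.csv",
                              package = "ratresp"),
                  stringsAsFactors = FALSE)
}
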