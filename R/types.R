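# Core S3 containers shared across the pipeline.

#' Uniformly sampled scalar signal
#'
#' Lightweight container for every 1-D signal in the pipeline: the raw area
#' signal, the denoised and band-passed respiration signal, ECG traces and
#' the ECG-derived respiration (EDR) surrogate.
#'
#' @param values Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param units Label for the sample units (e.g. `"pixels"`, `"a.u."`).
#' @return An object of class `time_series` with fields `values`, `rate_hz`,
#'   `units`.
#' @export
time_series <- function(values, rate_hz, units = "a.u.") {
  stopifnot(is.numeric(values), length(rate_hz) == 1L, rate_hz > 0)
  if (anyNA(values)) stop("time_series values must not contain NA")
  structure(
    list(values = as.numeric(values), rate_hz = as.numeric(rate_hz),
         units = as.character(units)),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz (%.2f s), units: %s\n",
              length(x$values), x$rate_hz, length(x$values) / x$rate_hz,
              x$units))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param x A [time_series()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "time_series"))
  (seq_along(x$values) - 1L) / x$rate_hz
}

#' Per-frame binary masks with certainty scores
#'
#' Container for the output of a per-frame segmenter: an ordered list of
#' binary masks (logical matrices, all the same shape), one certainty score
#' per frame in \[0, 1\], the frame rate, and a per-frame validity flag.
#' A frame is valid when its score exceeds the gating threshold and the mask
#' is non-empty; flags are (re)computed by [gate_validity()].
#'
#' @param masks List of logical matrices of identical dimensions.
#' @param scores Numeric vector in \[0, 1\], one per frame.
#' @param fps Frame rate in frames per second.
#' @param valid Optional logical vector; defaults to all frames with a
#'   non-empty mask.
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(masks, scores, fps, valid = NULL) {
  stopifnot(is.list(masks), length(masks) == length(scores), fps > 0)
  if (length(masks) == 0L) stop("mask_sequence requires at least one frame")
  dims <- dim(masks[[1L]])
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!is.matrix(m)) stop("mask ", i, " is not a matrix")
    if (!identical(dim(m), dims)) stop("mask ", i, " has mismatched shape")
    if (!is.logical(m)) masks[[i]] <- m != 0
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (is.null(valid)) valid <- vapply(masks, any, logical(1L))
  stopifnot(length(valid) == length(masks))
  structure(
    list(masks = masks, scores = as.numeric(scores), fps = as.numeric(fps),
         valid = as.logical(valid)),
    class = "mask_sequence"
  )
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$masks[[1L]])
  cat(sprintf("<mask_sequence> %d frames of %dx%d @ %g fps, %d valid\n",
              length(x$masks), d[1L], d[2L], x$fps, sum(x$valid)))
  invisible(x)
}

#' @export
length.mask_sequence <- function(x) length(x$masks)

#' Per-frame region geometry extracted from a mask sequence
#'
#' Holds, per frame: foreground pixel count (`area`), unweighted centroid in
#' 0-based pixel coordinates (`com_x` = column, `com_y` = row), the tight
#' half-open bounding box `(row_min, col_min, row_max, col_max)`, a validity
#' flag, and after [fill_gaps()] a `segment` id per frame (NA inside gaps too
#' long to interpolate).
#'
#' @param area,com_x,com_y Numeric vectors, one value per frame (NA when
#'   invalid).
#' @param bbox Integer matrix with one row per frame and columns
#'   `row_min, col_min, row_max, col_max` (NA when invalid).
#' @param valid Logical vector per frame.
#' @param fps Frame rate in frames per second.
#' @param segment Optional integer vector of analysis-segment ids.
#' @return An object of class `region_track`.
#' @export
region_track <- function(area, com_x, com_y, bbox, valid, fps,
                         segment = NULL) {
  n <- length(area)
  stopifnot(length(com_x) == n, length(com_y) == n, length(valid) == n,
            nrow(bbox) == n, fps > 0)
  if (is.null(segment)) segment <- rep(1L, n)
  structure(
    list(area = as.numeric(area), com_x = as.numeric(com_x),
         com_y = as.numeric(com_y), bbox = bbox, valid = as.logical(valid),
         fps = as.numeric(fps), segment = as.integer(segment)),
    class = "region_track"
  )
}

#' @export
print.region_track <- function(x, ...) {
  cat(sprintf(
    "<region_track> %d frames @ %g fps, %d valid, %d segment(s)\n",
    length(x$area), x$fps, sum(x$valid),
    length(unique(stats::na.omit(x$segment)))))
  invisible(x)
}
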