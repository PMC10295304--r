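# Readers and writers for the external formats: per-frame PNG mask stacks
# with a JSON sidecar, intensity-frame directories, two-column ECG CSV, and
# CSV/JSON result files.

#' Write a mask sequence as numbered PNGs plus a JSON sidecar
#'
#' Masks are written as 8-bit grayscale PNGs (0/255) named
#' `frame_00001.png`, ...; `sequence.json` records fps, scores and, when
#' given, the generator truth table.
#'
#' @param seq A [mask_sequence()].
#' @param dir Output directory (created if missing).
#' @param truth Optional truth data frame (e.g. from
#'   [generate_breathing_masks()]).
#' @return `dir`, invisibly.
#' @export
write_mask_sequence <- function(seq, dir, truth = NULL) {
  stopifnot(inherits(seq, "mask_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$masks)) {
    png::writePNG(seq$masks[[i]] * 1,
                  file.path(dir, sprintf("frame_%05d.png", i)))
  }
  side <- list(fps = seq$fps, scores = seq$scores,
               n_frames = length(seq$masks))
  if (!is.null(truth)) {
    side$truth <- truth
    side$rr_true <- attr(truth, "rr_true")
  }
  jsonlite::write_json(side, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a mask sequence written by [write_mask_sequence()]
#'
#' @param dir Directory of `frame_*.png` files and `sequence.json`.
#' @return A list with `masks` (a [mask_sequence()]) and `truth` (data frame
#'   or NULL).
#' @export
read_mask_sequence <- function(dir) {
  side_path <- file.path(dir, "sequence.json")
  if (!file.exists(side_path))
    stop("no sequence.json sidecar in '", dir, "'")
  side <- jsonlite::fromJSON(side_path)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frame_*.png files in '", dir, "'")
  masks <- lapply(files, function(f) png::readPNG(f) > 0.5)
  truth <- NULL
  if (!is.null(side$truth)) {
    truth <- as.data.frame(side$truth)
    attr(truth, "rr_true") <- side$rr_true
  }
  list(masks = mask_sequence(masks, scores = side$scores, fps = side$fps),
       truth = truth)
}

#' Read a directory of intensity frames
#'
#' Loads PNG frames in lexicographic order as grayscale matrices (RGB is
#' reduced to Rec.601 luminance). Video containers are not decoded; extract
#' frames to PNG first (e.g. with ffmpeg).
#'
#' @param dir Directory of `.png` frames.
#' @return List of numeric matrices.
#' @export
read_frames_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    if (length(list.files(dir, pattern = "\\.(avi|mp4|AVI|MP4)$")) > 0L)
      stop("video files found in '", dir, "': decode to PNG frames first ",
           "(e.g. ffmpeg -i in.avi frame_%05d.png)")
    stop("no .png frames in '", dir, "'")
  }
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L)
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    img
  })
}

#' Write / read a two-column ECG CSV (time_s, amplitude)
#'
#' @param ecg A [time_series()].
#' @param path CSV path.
#' @return `read_ecg_csv()` returns a [time_series()]; the sampling rate is
#'   inferred from the median time step and the times must be uniform to
#'   within 1%.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "time_series"))
  utils::write.csv(data.frame(time_s = ts_times(ecg),
                              amplitude = ecg$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("ECG CSV '", path, "' must have columns time_s, amplitude")
  if (nrow(df) < 2L) stop("ECG CSV '", path, "' has fewer than 2 samples")
  dt <- diff(df$time_s)
  if (any(dt <= 0) || max(dt) / min(dt) > 1.01)
    stop("ECG CSV '", path, "' is not uniformly sampled")
  time_series(df$amplitude, 1 / stats::median(dt), units = "a.u.")
}

#' Write a time series as CSV (sample_index, time_s, value)
#'
#' @param x A [time_series()].
#' @param path CSV path.
#' @export
write_time_series_csv <- function(x, path) {
  stopifnot(inherits(x, "time_series"))
  utils::write.csv(data.frame(sample_index = seq_along(x$values) - 1L,
                              time_s = ts_times(x), value = x$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an instantaneous-RR series as CSV (time_s, rr_breaths_per_min)
#'
#' @param rr An `rr_series` from [instantaneous_rr()].
#' @param path CSV path.
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(time_s = rr$times,
                              rr_breaths_per_min = rr$values),
                   path, row.names = FALSE)
  invisible(path)
}
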