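# End-to-end binding: gated masks -> region track -> gap handling -> area
# signal -> noise-subspace projection -> band-pass -> gradient clipping ->
# breath peaks -> respiratory rate, per analysis segment.

#' Extract the respiratory rate from a mask sequence
#'
#' Runs the full camera branch: validity gating, region tracking, gap
#' interpolation / segmentation, and per segment the area signal R, its
#' projection off the center-of-mass noise subspace, zero-phase Butterworth
#' band-pass, gradient clipping, breath-peak detection and
#' `f_RR = 60/d_peak`. Instantaneous rates from all segments are pooled;
#' `mean_rr` is their arithmetic mean.
#'
#' @param seq A [mask_sequence()] (gated or not; gating is applied here).
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage counts to `message()`.
#' @return A list: `rr` (pooled `times`/`values`), `mean_rr`, `n_breaths`,
#'   `coverage_fraction` (fraction of frames contributing to analysis
#'   segments), `segments` (per-segment results) and `counts` (per-stage
#'   bookkeeping).
#' @export
extract_rr_from_masks <- function(seq, config = pipeline_config(),
                                  verbose = FALSE) {
  stopifnot(inherits(seq, "mask_sequence"))
  log_ <- function(...) if (verbose) message(sprintf(...))
  n_frames <- length(seq$masks)
  log_("frames: %d @ %g fps", n_frames, seq$fps)

  seq <- gate_validity(seq, config$score_threshold)
  log_("valid after gating (> %.2f): %d", config$score_threshold,
       sum(seq$valid))
  track <- track_region(seq)
  track <- fill_gaps(track, max_gap_s = config$gap_max_s)
  seg_ids <- sort(unique(stats::na.omit(track$segment)))

  min_len <- 3L * ceiling(track$fps / config$band_low_hz)
  seg_results <- list()
  all_times <- numeric(); all_values <- numeric()
  n_used <- 0L; n_peaks <- 0L
  for (s in seg_ids) {
    sel <- which(!is.na(track$segment) & track$segment == s)
    if (length(sel) < min_len) {
      log_("segment %d: %d frames, too short, skipped", s, length(sel))
      next
    }
    r <- area_signal(track, s)
    q <- build_noise_subspace(track, s)
    z <- denoise_projection(r, q)
    f <- bandpass_respiration(z, config$band_low_hz, config$band_high_hz,
                              config$butter_order)
    # the clip limit is dimensionless: standardize to unit variance so
    # 1.5/sample marks impulsive jumps, not the breathing slope itself
    sdv <- stats::sd(f$values)
    if (sdv > 0) f$values <- f$values / sdv
    f <- clip_gradient(f, config$clip_limit)
    peaks <- detect_breath_peaks(f, outlier_frac = config$outlier_frac)
    rr <- instantaneous_rr(peaks)
    t0 <- (sel[1L] - 1L) / track$fps
    log_("segment %d: %d frames, %d breath peaks, mean RR %s", s,
         length(sel), length(peaks$maxima),
         if (isTRUE(rr$empty)) "n/a" else sprintf("%.2f", rr$mean_rr))
    seg_results[[length(seg_results) + 1L]] <-
      list(segment = s, n_frames = length(sel), start_s = t0,
           signal = f, peaks = peaks, rr = rr)
    if (!isTRUE(rr$empty)) {
      all_times <- c(all_times, t0 + rr$times)
      all_values <- c(all_values, rr$values)
    }
    n_used <- n_used + length(sel)
    n_peaks <- n_peaks + length(peaks$maxima)
  }
  list(
    rr = list(times = all_times, values = all_values),
    mean_rr = if (length(all_values) > 0L) mean(all_values) else NA_real_,
    n_breaths = n_peaks,
    coverage_fraction = n_used / n_frames,
    segments = seg_results,
    counts = list(n_frames = n_frames, n_valid = sum(seq$valid),
                  n_segments = length(seg_results), n_frames_used = n_used)
  )
}

#' Run the full ECG reference branch
#'
#' Notch preprocessing, rat-tuned R-peak detection, EDR reconstruction from
#' R-peak amplitude modulation, and the EDR respiratory rate.
#'
#' @param ecg A [time_series()] of ECG amplitude.
#' @param config A [pipeline_config()].
#' @return A list: `peaks` ([r_peak_set()]), `edr` ([time_series()]), `rr`
#'   (`rr_series`) and `mean_rr`.
#' @export
extract_rr_from_ecg <- function(ecg, config = pipeline_config()) {
  clean <- preprocess_ecg(ecg, powerline_hz = config$ecg_powerline_hz)
  peaks <- detect_r_peaks(clean,
                          smoothwindow = config$ecg_smoothwindow,
                          avgwindow = config$ecg_avgwindow,
                          min_delay = config$ecg_min_delay,
                          min_qrs = config$ecg_min_qrs,
                          gradthresh_weight = config$ecg_gradthresh_weight)
  edr <- extract_edr(peaks, rate_out = config$edr_rate_out,
                     band = c(config$band_low_hz, config$band_high_hz),
                     lowpass_hz = config$edr_lowpass_hz)
  rr <- edr_rate(edr, outlier_frac = config$outlier_frac)
  list(peaks = peaks, edr = edr, rr = rr, mean_rr = rr$mean_rr)
}
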