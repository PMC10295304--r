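# From gated masks to a conditioned respiration signal: per-frame region
# geometry, gap handling, the raw area signal R, projection of R off a
# noise subspace built from center-of-mass motion, Butterworth band-pass,
# and gradient clipping with interpolation.

# Least-squares line removal (slope and intercept).
detrend_linear <- function(v) {
  tt <- seq_along(v)
  stats::lm.fit(cbind(1, tt), v)$residuals
}

#' Extract per-frame region geometry from a mask sequence
#'
#' For each valid frame: foreground pixel count (the raw respiration sample),
#' the unweighted centroid in 0-based (col = x, row = y) pixel coordinates,
#' and the tight half-open bounding box. Invalid frames carry NA geometry.
#'
#' @param seq A gated [mask_sequence()].
#' @return A [region_track()].
#' @export
track_region <- function(seq) {
  stopifnot(inherits(seq, "mask_sequence"))
  n <- length(seq$masks)
  if (!any(seq$valid)) stop("all frames are invalid; nothing to track")
  area <- com_x <- com_y <- rep(NA_real_, n)
  bbox <- matrix(NA_integer_, n, 4L,
                 dimnames = list(NULL, c("row_min", "col_min",
                                         "row_max", "col_max")))
  for (i in seq_len(n)) {
    if (!seq$valid[i]) next
    idx <- which(seq$masks[[i]], arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    area[i] <- nrow(idx)
    com_y[i] <- mean(idx[, 1L]) - 1
    com_x[i] <- mean(idx[, 2L]) - 1
    bbox[i, ] <- c(min(idx[, 1L]) - 1L, min(idx[, 2L]) - 1L,
                   max(idx[, 1L]), max(idx[, 2L]))
  }
  region_track(area, com_x, com_y, bbox, valid = seq$valid & !is.na(area),
               fps = seq$fps)
}

#' Interpolate short invalid runs; split long ones into segments
#'
#' Runs of invalid frames no longer than `max_gap_s * fps` that are bounded
#' by valid frames are filled by linear interpolation of area and centroid
#' and marked valid. Longer (or unbounded) runs split the recording into
#' independent analysis segments, numbered in `track$segment` (NA inside
#' unfilled gaps).
#'
#' @param track A [region_track()].
#' @param max_gap_s Longest interpolable gap in seconds (default 0.5).
#' @return The gap-filled track.
#' @export
fill_gaps <- function(track, max_gap_s = 0.5) {
  stopifnot(inherits(track, "region_track"))
  n <- length(track$area)
  valid <- track$valid
  max_run <- floor(max_gap_s * track$fps)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  filled <- valid
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    interior <- k > 1L && k < length(r$lengths)
    if (interior && r$lengths[k] <= max_run) {
      i0 <- begs[k] - 1L; i1 <- ends[k] + 1L
      sel <- begs[k]:ends[k]
      w <- (sel - i0) / (i1 - i0)
      for (f in c("area", "com_x", "com_y"))
        track[[f]][sel] <- (1 - w) * track[[f]][i0] + w * track[[f]][i1]
      filled[sel] <- TRUE
    }
  }
  seg <- rep(NA_integer_, n)
  rf <- rle(filled)
  e2 <- cumsum(rf$lengths); b2 <- e2 - rf$lengths + 1L
  sid <- 0L
  for (k in seq_along(rf$lengths)) {
    if (!rf$values[k]) next
    sid <- sid + 1L
    seg[b2[k]:e2[k]] <- sid
  }
  track$valid <- filled
  track$segment <- seg
  track
}

#' Area signal of one analysis segment
#'
#' @param track A gap-filled [region_track()].
#' @param segment Segment id (default 1).
#' @return A [time_series()] of the per-frame foreground area in pixels.
#' @export
area_signal <- function(track, segment = 1L) {
  sel <- which(!is.na(track$segment) & track$segment == segment)
  if (length(sel) == 0L) stop("no frames in segment ", segment)
  time_series(track$area[sel], track$fps, units = "pixels")
}

#' Build the noise-regressor matrix from center-of-mass motion
#'
#' Four sample-aligned nuisance channels describing gross body motion: the
#' linearly detrended centroid x and y trajectories and their first
#' differences (first sample duplicated to preserve length; each column
#' detrended so it carries no best-fit line).
#'
#' @param track A gap-filled [region_track()].
#' @param segment Segment id (default 1).
#' @return A `noise_regressors` object: numeric matrix (n x 4) with columns
#'   `com_x`, `com_y`, `d_com_x`, `d_com_y`.
#' @export
build_noise_subspace <- function(track, segment = 1L) {
  sel <- which(!is.na(track$segment) & track$segment == segment)
  if (length(sel) < 3L) stop("need at least 3 frames to build regressors")
  cx <- detrend_linear(track$com_x[sel])
  cy <- detrend_linear(track$com_y[sel])
  dcx <- detrend_linear(c(diff(cx)[1L], diff(cx)))
  dcy <- detrend_linear(c(diff(cy)[1L], diff(cy)))
  q <- cbind(com_x = cx, com_y = cy, d_com_x = dcx, d_com_y = dcy)
  structure(q, class = c("noise_regressors", class(q)))
}

#' Project a signal off its noise subspace
#'
#' Removes from R its least-squares projection onto the column space of Q:
#' `Z = R - Q (Q'Q)^+ Q' R`, computed through the SVD of Q so rank-deficient
#' regressor sets (e.g. a constant centroid) are handled. The residual is
#' orthogonal to every regressor, and projecting twice changes nothing.
#'
#' @param r A [time_series()] (the raw area signal R).
#' @param q Numeric matrix of sample-aligned noise regressors (may be
#'   all-zero, in which case Z = R).
#' @return A [time_series()] Z of the same length and rate.
#' @export
denoise_projection <- function(r, q) {
  stopifnot(inherits(r, "time_series"))
  q <- unclass(q)
  stopifnot(is.matrix(q))
  v <- r$values
  if (nrow(q) != length(v))
    stop("regressor length (", nrow(q), ") != signal length (", length(v), ")")
  sv <- svd(q)
  tol <- max(sv$d) * max(dim(q)) * .Machine$double.eps
  keep <- sv$d > tol
  z <- if (!any(keep)) v else {
    u <- sv$u[, keep, drop = FALSE]
    v - u %*% crossprod(u, v)
  }
  time_series(as.numeric(z), r$rate_hz, units = r$units)
}

#' Band-pass the respiration signal
#'
#' Second-order Butterworth band-pass over the rodent respiration band
#' (default 1--3.3 Hz, i.e. 60--200 breaths/min), applied forward-backward
#' (zero phase) so breath-peak timing is preserved; the mean is removed
#' first.
#'
#' @param z A [time_series()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order of the analog prototype (default 2).
#' @return The filtered [time_series()].
#' @export
bandpass_respiration <- function(z, low_hz = 1, high_hz = 3.3, order = 2L) {
  stopifnot(inherits(z, "time_series"), low_hz > 0, high_hz > low_hz)
  fs <- z$rate_hz
  if (fs <= 2 * high_hz)
    stop("sampling rate ", fs, " Hz too low for a ", high_hz, " Hz band edge")
  settle <- ceiling(fs / low_hz)   # one period of the slowest band component
  if (length(z$values) < 3L * settle)
    stop("signal shorter than 3x the filter's settled length (",
         3L * settle, " samples)")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- signal::filtfilt(bf, z$values - mean(z$values))
  time_series(out, fs, units = z$units)
}

#' Clip excessive sample-to-sample gradients and re-interpolate
#'
#' Both endpoints of every first difference whose magnitude exceeds `limit`
#' are invalidated and replaced by linear interpolation between the nearest
#' surviving samples; flagged edges take the nearest surviving value.
#'
#' @param x A [time_series()].
#' @param limit Gradient limit in signal units per sample (default 1.5).
#' @return The clipped-and-filled [time_series()].
#' @export
clip_gradient <- function(x, limit = 1.5) {
  stopifnot(inherits(x, "time_series"), limit > 0)
  v <- x$values
  n <- length(v)
  if (n < 2L) return(x)
  d <- abs(diff(v))
  bad <- rep(FALSE, n)
  over <- which(d > limit)
  bad[over] <- TRUE
  bad[over + 1L] <- TRUE
  if (all(bad)) stop("every sample exceeds the gradient limit")
  if (!any(bad)) return(x)
  keep <- which(!bad)
  v <- stats::approx(keep, v[keep], xout = seq_len(n), rule = 2)$y
  time_series(v, x$rate_hz, units = x$units)
}

#' Shift masks so all centroids coincide
#'
#' Integer-pixel translation of every valid mask so its centroid lands on
#' the frame center. The area signal is translation-invariant, so this does
#' not change R; it is kept for mask-stack export and visual QC.
#'
#' @param seq A [mask_sequence()].
#' @param track The matching [region_track()].
#' @return A [mask_sequence()] of aligned masks.
#' @export
align_masks_com <- function(seq, track) {
  stopifnot(inherits(seq, "mask_sequence"), inherits(track, "region_track"))
  d <- dim(seq$masks[[1L]])
  ctr <- (d - 1) / 2
  out <- seq
  for (i in seq_along(seq$masks)) {
    if (!track$valid[i] || is.na(track$com_x[i])) next
    dr <- round(ctr[1L] - track$com_y[i])
    dc <- round(ctr[2L] - track$com_x[i])
    m <- seq$masks[[i]]
    shifted <- matrix(FALSE, d[1L], d[2L])
    src_r <- seq_len(d[1L]) - dr
    src_c <- seq_len(d[2L]) - dc
    ok_r <- src_r >= 1L & src_r <= d[1L]
    ok_c <- src_c >= 1L & src_c <= d[2L]
    shifted[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out$masks[[i]] <- shifted
  }
  out
}
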