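# Ground-truthed synthetic inputs: a breathing elliptical "rat" blob whose
# projected area oscillates at a set respiratory frequency, and a rat-like
# ECG whose R-peak amplitudes are modulated at the respiratory frequency.
# Both carry exact analytic truth so every downstream stage is testable
# without animal recordings.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic breathing-blob recording
#'
#' Describes an elliptical region whose rasterized area oscillates at the
#' true respiratory rate, whose center follows a slow sinusoidal drift, and
#' which undergoes instantaneous center jumps (motion artifacts) at given
#' times. Artifacts displace the center, not the area: motion corrupts the
#' signal through tracking, not through true thorax size.
#'
#' @param duration_s Recording length in seconds.
#' @param fps Frame rate, frames/s (default 60). Must exceed twice the
#'   respiratory frequency.
#' @param frame_shape Integer `(rows, cols)` of each frame.
#' @param rr_true True respiratory rate, breaths/min (60--200 for the rat
#'   band).
#' @param area_mean Mean ellipse area, pixels.
#' @param area_amplitude_frac Fractional peak area modulation (< 1).
#' @param drift_amplitude Amplitude of the slow sinusoidal center drift,
#'   pixels.
#' @param artifact_times Times (s) of instantaneous center jumps.
#' @param artifact_shift Size of each jump, pixels.
#' @param noise_sd SD of white noise added to the target area, pixels^2
#'   (realized by jittering both semi-axes so masks stay valid ellipses).
#' @param aspect Ratio of the column semi-axis to the row semi-axis
#'   (elongated, rat-like, default 2).
#' @param seed Integer RNG seed.
#' @return A `blob_spec` list.
#' @export
blob_spec <- function(duration_s, fps = 60, frame_shape = c(120L, 160L),
                      rr_true = 96, area_mean = 1500,
                      area_amplitude_frac = 0.05, drift_amplitude = 4,
                      artifact_times = numeric(), artifact_shift = 8,
                      noise_sd = 0, aspect = 2, seed = 1L) {
  stopifnot(duration_s > 0, fps > 0, length(frame_shape) == 2L,
            all(frame_shape > 0), rr_true > 0, area_mean > 0,
            area_amplitude_frac >= 0, drift_amplitude >= 0,
            artifact_shift >= 0, noise_sd >= 0, aspect > 0)
  if (area_amplitude_frac >= 1)
    stop("area_amplitude_frac must be < 1 (area must stay positive)")
  if (fps <= 2 * rr_true / 60)
    stop("fps must exceed twice the respiratory frequency (Nyquist)")
  structure(
    list(duration_s = duration_s, fps = fps,
         frame_shape = as.integer(frame_shape), rr_true = rr_true,
         area_mean = area_mean, area_amplitude_frac = area_amplitude_frac,
         drift_amplitude = drift_amplitude,
         artifact_times = as.numeric(artifact_times),
         artifact_shift = artifact_shift, noise_sd = noise_sd,
         aspect = aspect, seed = as.integer(seed)),
    class = "blob_spec"
  )
}

# Rasterize one ellipse: pixel (r, c) (0-based) is foreground iff its center
# satisfies ((c-cx)/a)^2 + ((r-cy)/b)^2 <= 1.
rasterize_ellipse <- function(frame_shape, cx, cy, a, b) {
  m <- matrix(FALSE, frame_shape[1L], frame_shape[2L])
  r0 <- max(0L, floor(cy - b)); r1 <- min(frame_shape[1L] - 1L, ceiling(cy + b))
  c0 <- max(0L, floor(cx - a)); c1 <- min(frame_shape[2L] - 1L, ceiling(cx + a))
  if (r1 < r0 || c1 < c0) return(m)
  rr <- r0:r1; cc <- c0:c1
  inside <- outer(((rr - cy) / b)^2, ((cc - cx) / a)^2, `+`) <= 1
  m[rr + 1L, cc + 1L] <- inside
  m
}

#' Generate a synthetic breathing-blob mask sequence
#'
#' Rasterizes, per frame, an ellipse whose analytic area follows
#' `area_mean * (1 + area_amplitude_frac * sin(2*pi*(rr_true/60)*t))`
#' (plus optional white noise), centered on a slowly drifting trajectory
#' with step jumps at the artifact times. The semi-axes scale jointly so
#' that the ellipse area equals the (noisy) analytic target; a pixel is
#' inside iff its center satisfies the ellipse inequality.
#'
#' @param spec A [blob_spec()].
#' @return A list with `masks` (a [mask_sequence()] with per-frame score 1)
#'   and `truth`, a data frame of per-frame analytic `area`, `com_x`,
#'   `com_y`, `time_s`, plus attribute `rr_true`.
#' @export
generate_breathing_masks <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  n <- round(spec$duration_s * spec$fps)
  t <- (seq_len(n) - 1L) / spec$fps
  f_resp <- spec$rr_true / 60

  area <- spec$area_mean *
    (1 + spec$area_amplitude_frac * sin(2 * pi * f_resp * t))
  if (spec$noise_sd > 0)
    area <- area + with_seed(spec$seed, stats::rnorm(n, sd = spec$noise_sd))
  if (any(area <= 0)) stop("noise drove the target area non-positive")

  # slow drift well below the respiration band; x and y in quadrature
  f_drift <- 0.1
  rows <- spec$frame_shape[1L]; cols <- spec$frame_shape[2L]
  cx <- (cols - 1) / 2 + spec$drift_amplitude * sin(2 * pi * f_drift * t)
  cy <- (rows - 1) / 2 + spec$drift_amplitude * cos(2 * pi * f_drift * t)
  # persistent step jumps, alternating sign so the blob stays in frame
  for (k in seq_along(spec$artifact_times)) {
    on <- t >= spec$artifact_times[k]
    sgn <- if (k %% 2 == 1) 1 else -1
    cx[on] <- cx[on] + sgn * spec$artifact_shift
  }

  a <- sqrt(area * spec$aspect / pi)   # column semi-axis
  b <- a / spec$aspect                 # row semi-axis
  bad <- which(cx - a < 0 | cx + a > cols - 1 | cy - b < 0 | cy + b > rows - 1)
  if (length(bad) > 0)
    stop(sprintf("ellipse exceeds frame bounds at frame %d (t = %.3f s)",
                 bad[1L], t[bad[1L]]))

  masks <- vector("list", n)
  for (i in seq_len(n))
    masks[[i]] <- rasterize_ellipse(spec$frame_shape, cx[i], cy[i], a[i], b[i])

  truth <- data.frame(frame = seq_len(n), time_s = t, area = area,
                      com_x = cx, com_y = cy)
  attr(truth, "rr_true") <- spec$rr_true
  list(masks = mask_sequence(masks, scores = rep(1, n), fps = spec$fps),
       truth = truth)
}

#' Specification of a synthetic rat ECG
#'
#' A train of narrow biphasic QRS-like pulses at the cardiac rate whose
#' R amplitudes are modulated at the respiratory frequency — the
#' amplitude-modulation mechanism that ECG-derived respiration exploits —
#' plus optional 50 Hz powerline interference and white noise.
#'
#' @param duration_s Recording length, seconds.
#' @param rate_hz Sampling rate, samples/s (default 1000; rat QRS is
#'   10--20 ms wide).
#' @param hr_bpm Heart rate, beats/min (rats: roughly 300--420).
#' @param rr_true True respiratory rate, breaths/min; must be below
#'   `hr_bpm`.
#' @param am_depth Fractional respiratory amplitude modulation in (0, 1).
#' @param powerline_amp Amplitude of a 50 Hz sinusoid.
#' @param noise_sd SD of additive white noise.
#' @param seed Integer RNG seed.
#' @return An `ecg_spec` list.
#' @export
ecg_spec <- function(duration_s, rate_hz = 1000, hr_bpm = 360, rr_true = 96,
                     am_depth = 0.3, powerline_amp = 0, noise_sd = 0,
                     seed = 1L) {
  stopifnot(duration_s > 0, rate_hz > 0, hr_bpm > 0, rr_true > 0,
            am_depth >= 0, am_depth < 1, powerline_amp >= 0, noise_sd >= 0)
  if (hr_bpm <= rr_true)
    stop("hr_bpm must exceed rr_true (cardiac fundamental above respiration)")
  structure(
    list(duration_s = duration_s, rate_hz = rate_hz, hr_bpm = hr_bpm,
         rr_true = rr_true, am_depth = am_depth,
         powerline_amp = powerline_amp, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "ecg_spec"
  )
}

#' Generate a synthetic rat ECG with respiratory amplitude modulation
#'
#' Pulses are placed at exact intervals of `60/hr_bpm` seconds (first pulse
#' half an interval in, so a whole number of beats fits the recording); each
#' beat is a sharp positive R deflection followed by a smaller negative S
#' deflection, scaled by `1 + am_depth*sin(2*pi*(rr_true/60)*t_peak)`.
#'
#' @param spec An [ecg_spec()].
#' @return A list with `ecg` (a [time_series()]) and `truth`, a data frame
#'   of exact `peak_time_s`, `peak_index` (1-based sample) and the applied
#'   `amplitude` factor per beat, with attribute `rr_true`.
#' @export
generate_rat_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_spec"))
  n <- round(spec$duration_s * spec$rate_hz)
  t <- (seq_len(n) - 1L) / spec$rate_hz
  ibi <- 60 / spec$hr_bpm
  n_beats <- floor(spec$duration_s / ibi)
  peak_times <- (seq_len(n_beats) - 0.5) * ibi
  amp <- 1 + spec$am_depth * sin(2 * pi * (spec$rr_true / 60) * peak_times)

  # biphasic QRS template: R gaussian (sigma 4 ms) + S trough 8 ms later
  sig_r <- 0.004
  x <- numeric(n)
  half <- ceiling(5 * sig_r * spec$rate_hz)
  for (k in seq_len(n_beats)) {
    c_idx <- round(peak_times[k] * spec$rate_hz) + 1L
    i0 <- max(1L, c_idx - half); i1 <- min(n, c_idx + 3L * half)
    tau <- (t[i0:i1] - peak_times[k])
    pulse <- exp(-tau^2 / (2 * sig_r^2)) -
      0.3 * exp(-(tau - 0.008)^2 / (2 * sig_r^2))
    x[i0:i1] <- x[i0:i1] + amp[k] * pulse
  }
  if (spec$powerline_amp > 0)
    x <- x + spec$powerline_amp * sin(2 * pi * 50 * t)
  if (spec$noise_sd > 0)
    x <- x + with_seed(spec$seed, stats::rnorm(n, sd = spec$noise_sd))

  truth <- data.frame(peak_time_s = peak_times,
                      peak_index = round(peak_times * spec$rate_hz) + 1L,
                      amplitude = amp)
  attr(truth, "rr_true") <- spec$rr_true
  list(ecg = time_series(x, spec$rate_hz, units = "a.u."), truth = truth)
}
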