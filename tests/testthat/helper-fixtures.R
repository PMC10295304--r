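# Shared fixtures and independent oracles, built in code at test time.

# Small, fast breathing-blob spec for pipeline tests.
small_blob <- function(rr_true = 96, duration_s = 30, noise_sd = 0,
                       artifact_times = numeric(), seed = 1L, ...) {
  blob_spec(duration_s = duration_s, fps = 60,
            frame_shape = c(120L, 160L), rr_true = rr_true,
            area_mean = 1500, area_amplitude_frac = 0.05,
            drift_amplitude = 4, artifact_times = artifact_times,
            artifact_shift = 8, noise_sd = noise_sd, seed = seed, ...)
}

# Independent periodogram oracle: dominant frequency (Hz) of a series by a
# plain FFT, and the bin width.
dominant_freq <- function(v, fs) {
  v <- v - mean(v)
  n <- length(v)
  p <- abs(stats::fft(v))^2
  half <- 2:(n %/% 2)
  freq <- (half - 1) * fs / n
  list(freq = freq[which.max(p[half])], bin = fs / n)
}

# Single-tone amplitude at frequency f by least squares on a sin/cos basis
# (exact for a steady tone, robust to other components).
tone_amplitude <- function(v, fs, f) {
  t <- (seq_along(v) - 1) / fs
  x <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::lm.fit(x, v - mean(v))$coefficients
  sqrt(sum(cf^2))
}

# Shoelace polygon area oracle.
shoelace_area <- function(verts) {
  x <- verts[, 1L]; y <- verts[, 2L]
  n <- nrow(verts)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Brute-force oracle for breath-peak detection: local extremum between
# consecutive sign changes of the detrended signal, no outlier logic.
brute_force_peaks <- function(v) {
  tt <- seq_along(v)
  v <- v - stats::lm.fit(cbind(1, tt), v)$coefficients %*% rbind(1, tt)
  v <- as.numeric(v)
  pos <- v > 0
  maxima <- integer(); minima <- integer()
  run_start <- 1L
  for (i in 2:length(v)) {
    if (pos[i] != pos[i - 1L]) {
      span <- run_start:(i - 1L)
      if (run_start > 1L) {  # drop the leading partial run
        if (pos[i - 1L]) maxima <- c(maxima, span[which.max(v[span])])
        else minima <- c(minima, span[which.min(v[span])])
      }
      run_start <- i
    }
  }
  list(maxima = maxima, minima = minima)
}

# A steady unit sine as a time_series.
sine_ts <- function(f, fs, duration_s, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  time_series(sin(2 * pi * f * t + phase), fs)
}
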