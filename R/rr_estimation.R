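# Breath-peak detection on a conditioned respiration (or EDR) signal and
# instantaneous / mean respiratory rate, after an electrical-impedance-
# tomography-style zero-crossing scheme: detrend, find zero crossings, take
# one extremum per half-cycle, then reject peaks whose spacing to a
# neighbour is implausibly short.

#' Breath peaks of a respiration signal
#'
#' @param maxima,minima Strictly increasing 1-based sample indices.
#' @param rate_hz Sampling rate of the source signal.
#' @return A `breath_peaks` object.
#' @export
breath_peaks <- function(maxima, minima, rate_hz) {
  stopifnot(rate_hz > 0,
            !is.unsorted(maxima, strictly = TRUE),
            !is.unsorted(minima, strictly = TRUE))
  structure(list(maxima = as.integer(maxima), minima = as.integer(minima),
                 rate_hz = as.numeric(rate_hz)),
            class = "breath_peaks")
}

#' @export
print.breath_peaks <- function(x, ...) {
  cat(sprintf("<breath_peaks> %d maxima, %d minima @ %g Hz\n",
              length(x$maxima), length(x$minima), x$rate_hz))
  invisible(x)
}

# Drop peaks forming implausibly short inter-peak intervals: while any
# interval is shorter than frac * median(intervals), remove the
# lower-amplitude member of the first offending pair and re-pair.
reject_interval_outliers <- function(idx, values, frac) {
  while (length(idx) >= 3L) {
    iv <- diff(idx)
    med <- stats::median(iv)
    bad <- which(iv < frac * med)
    if (length(bad) == 0L) break
    i <- bad[1L]
    drop <- if (abs(values[idx[i]]) < abs(values[idx[i + 1L]])) i else i + 1L
    idx <- idx[-drop]
  }
  idx
}

#' Detect breath peaks by zero-crossing search
#'
#' The signal is detrended by subtracting its least-squares line; sign
#' changes mark the zero crossings; between each rising crossing and the
#' next falling one the maximum sample is taken (and the minimum between a
#' falling and the next rising crossing); finally peaks whose distance to a
#' neighbouring peak falls below `outlier_frac` times the median inter-peak
#' interval are rejected (the smaller-amplitude member of each offending
#' pair is dropped and the survivors re-paired). Detection depends only on
#' the signal's shape, so positive rescaling leaves the result unchanged.
#'
#' @param x A conditioned [time_series()].
#' @param outlier_frac Fraction of the median inter-peak interval below
#'   which a spacing is an outlier (default 0.3).
#' @return A [breath_peaks()]; empty when the signal never crosses its
#'   trend line.
#' @export
detect_breath_peaks <- function(x, outlier_frac = 0.3) {
  stopifnot(inherits(x, "time_series"), outlier_frac >= 0)
  v <- detrend_linear(x$values)
  n <- length(v)
  pos <- v > 0
  rising <- which(!pos[-n] & pos[-1L])    # crossing between i and i+1, upward
  falling <- which(pos[-n] & !pos[-1L])
  if (length(rising) == 0L || length(falling) == 0L)
    return(breath_peaks(integer(), integer(), x$rate_hz))

  seg_extremum <- function(begs, ends, which_fn) {
    out <- integer()
    for (b in begs) {
      e <- ends[ends > b]
      if (length(e) == 0L) break
      e <- e[1L]
      span <- (b + 1L):e
      out <- c(out, span[which_fn(v[span])])
    }
    out
  }
  maxima <- seg_extremum(rising, falling, which.max)
  minima <- seg_extremum(falling, rising, which.min)
  maxima <- reject_interval_outliers(maxima, v, outlier_frac)
  minima <- reject_interval_outliers(minima, v, outlier_frac)
  breath_peaks(maxima, minima, x$rate_hz)
}

#' Instantaneous and mean respiratory rate from breath peaks
#'
#' For each pair of consecutive maxima, `d_peak` is the index difference
#' divided by the sampling rate (seconds) and the instantaneous rate is
#' `f_RR = 60 / d_peak` breaths/min, stamped at the pair's midpoint time.
#'
#' @param peaks A [breath_peaks()].
#' @return An `rr_series`: list with `times` (s), `values` (breaths/min),
#'   `mean_rr` (NA with an `empty` flag when fewer than two maxima exist)
#'   and `n_breaths`.
#' @export
instantaneous_rr <- function(peaks) {
  stopifnot(inherits(peaks, "breath_peaks"))
  m <- peaks$maxima
  if (length(m) < 2L) {
    return(structure(list(times = numeric(), values = numeric(),
                          mean_rr = NA_real_, n_breaths = length(m),
                          empty = TRUE),
                     class = "rr_series"))
  }
  d_peak <- diff(m) / peaks$rate_hz
  f_rr <- 60 / d_peak
  times <- (m[-length(m)] + m[-1L]) / 2
  times <- (times - 1) / peaks$rate_hz
  structure(list(times = times, values = f_rr, mean_rr = mean(f_rr),
                 n_breaths = length(m), empty = FALSE),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  if (isTRUE(x$empty)) cat("<rr_series> empty (fewer than 2 breath peaks)\n")
  else cat(sprintf("<rr_series> %d intervals, mean RR %.2f breaths/min\n",
                   length(x$values), x$mean_rr))
  invisible(x)
}
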