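# ECG preprocessing, rat-tuned R-peak detection, EDR reconstruction and its
# rate/spectrum.

test_that("notch suppresses 50 Hz and passes the EDR band", {
  fs <- 1000
  hum <- sine_ts(50, fs, 10)
  out <- preprocess_ecg(hum)
  expect_lt(tone_amplitude(out$values[2000:8000], fs, 50), 0.05)

  # 1.5 Hz content survives the notch and the 4 Hz EDR low-pass
  slow <- sine_ts(1.5, fs, 10)
  out2 <- preprocess_ecg(slow)
  expect_gt(tone_amplitude(out2$values[2000:8000], fs, 1.5), 0.95)
  lp <- signal::butter(2, 4 / (20 / 2), type = "low")
  v <- signal::filtfilt(lp, sin(2 * pi * 1.5 * seq(0, 10, by = 1 / 20)))
  amp <- tone_amplitude(v[40:160], 20, 1.5)
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)

  zero <- time_series(rep(0, 5000), fs)
  expect_equal(preprocess_ecg(zero)$values, rep(0, 5000))

  expect_warning(preprocess_ecg(time_series(rnorm(100), 60)), "notch")
})

test_that("R-peak detection recovers clean synthetic beats within a sample", {
  gen <- generate_rat_ecg(ecg_spec(duration_s = 60, hr_bpm = 360,
                                   rr_true = 96, am_depth = 0.3))
  peaks <- detect_r_peaks(preprocess_ecg(gen$ecg))
  expect_true(abs(length(peaks$indices) - 360L) <= 1L)
  matched <- vapply(gen$truth$peak_index, function(i)
    min(abs(peaks$indices - i)), numeric(1L))
  expect_true(all(matched <= 1))
})

test_that("R-peak detection: flat signal and min-delay merging", {
  flat <- time_series(rep(1, 2000), 1000)
  expect_length(detect_r_peaks(flat)$indices, 0L)

  # two pulses 0.05 s apart merge into one detection (0.1 s min delay)
  fs <- 1000
  t <- (0:(2 * fs)) / fs
  v <- exp(-(t - 1.0)^2 / (2 * 0.004^2)) + 0.8 * exp(-(t - 1.05)^2 / (2 * 0.004^2))
  p <- detect_r_peaks(time_series(v, fs))
  expect_length(p$indices, 1L)
  expect_equal(p$indices, 1001L, tolerance = 2)
})

test_that("R-peak recall stays >= 99% under realistic noise", {
  gen <- generate_rat_ecg(ecg_spec(duration_s = 60, hr_bpm = 360,
                                   rr_true = 96, am_depth = 0.3,
                                   powerline_amp = 0.1, noise_sd = 0.05,
                                   seed = 7L))
  peaks <- detect_r_peaks(preprocess_ecg(gen$ecg))
  expect_gte(r_peak_recall(peaks, gen$truth$peak_time_s), 0.99)
})

test_that("EDR reflects respiratory amplitude modulation, not cardiac rate", {
  mk <- function(depth, rr = 96) {
    gen <- generate_rat_ecg(ecg_spec(duration_s = 60, hr_bpm = 360,
                                     rr_true = rr, am_depth = depth))
    peaks <- detect_r_peaks(preprocess_ecg(gen$ecg))
    suppressWarnings(extract_edr(peaks))
  }
  edr_mod <- mk(0.3)
  edr_none <- mk(0)
  expect_lt(max(abs(edr_none$values)), 0.05 * max(abs(edr_mod$values)))

  edr100 <- mk(0.3, rr = 100)
  o <- dominant_freq(edr100$values, edr100$rate_hz)
  expect_lt(abs(o$freq - 100 / 60), o$bin + 1e-12)

  # identical amplitudes at uniform spacing -> EDR ~ 0
  idx <- seq(1L, 60000L, by = 166L)
  p <- r_peak_set(idx, rep(2, length(idx)), 1000)
  flat_edr <- suppressWarnings(extract_edr(p))
  expect_lt(max(abs(flat_edr$values)), 1e-6)
})

test_that("EDR amplitude scales linearly with modulation depth (small depths)", {
  rms <- function(x) sqrt(mean(x^2))
  mk <- function(depth) {
    gen <- generate_rat_ecg(ecg_spec(duration_s = 60, hr_bpm = 360,
                                     rr_true = 96, am_depth = depth))
    peaks <- detect_r_peaks(preprocess_ecg(gen$ecg))
    suppressWarnings(extract_edr(peaks))
  }
  r1 <- rms(mk(0.1)$values)
  r2 <- rms(mk(0.2)$values)
  expect_equal(r2 / r1, 2, tolerance = 0.1)
})

test_that("EDR errors when the beat rate cannot represent the band", {
  p <- r_peak_set(c(1L, 1001L, 2001L, 3001L), rep(1, 4), 1000)  # 1 Hz beats
  expect_error(extract_edr(p), "undersampled")
  expect_error(extract_edr(r_peak_set(1L, 1, 1000)), "4 R peaks")
})

test_that("EDR rate recovers the true respiratory rate end to end", {
  gen <- generate_rat_ecg(ecg_spec(duration_s = 60, hr_bpm = 360,
                                   rr_true = 96, am_depth = 0.3,
                                   powerline_amp = 0.05, noise_sd = 0.02,
                                   seed = 2L))
  res <- suppressWarnings(extract_rr_from_ecg(gen$ecg))
  expect_gt(res$mean_rr, 94); expect_lt(res$mean_rr, 98)

  # HR/RR separation: spectrum argmax at the respiratory, not cardiac, rate
  sp <- respiration_spectrum(res$edr)
  expect_true(sp$dominant)
  expect_lt(abs(sp$raw_peak_bpm - 96), sp$bin_bpm + 1e-9)

  # fundamental near 100 with a visible first harmonic near 200
  gen2 <- generate_rat_ecg(ecg_spec(duration_s = 60, hr_bpm = 420,
                                    rr_true = 100, am_depth = 0.4))
  res2 <- suppressWarnings(extract_rr_from_ecg(gen2$ecg))
  sp2 <- respiration_spectrum(res2$edr)
  expect_lt(abs(sp2$raw_peak_bpm - 100), sp2$bin_bpm + 1e-9)
  near <- function(f) sp2$power[abs(sp2$freq_bpm - f) <= sp2$bin_bpm + 1e-9]
  expect_gt(max(near(200)), 3 * stats::median(sp2$power))
  expect_gt(max(near(100)), max(near(200)))
})

test_that("spectrum flags white noise as having no dominant rate", {
  set.seed(99)
  x <- time_series(stats::rnorm(2400), 20)
  sp <- respiration_spectrum(x, seg_len = 128L)  # ~36 averaged segments
  expect_false(sp$dominant)
  expect_true(is.na(sp$peak_bpm))

  # single tone: argmax within one bin of 100 breaths/min
  tone <- sine_ts(100 / 60, 20, 60)
  spt <- respiration_spectrum(tone)
  expect_lt(abs(spt$raw_peak_bpm - 100), spt$bin_bpm + 1e-9)

  # fundamental plus weak first harmonic: both visible, fundamental dominant
  t <- seq(0, 60, by = 1 / 20)
  two <- time_series(sin(2 * pi * 1.6 * t) + 0.3 * sin(2 * pi * 3.2 * t), 20)
  sp2 <- respiration_spectrum(two)
  expect_lt(abs(sp2$raw_peak_bpm - 96), sp2$bin_bpm + 1e-9)
  near <- function(f) max(sp2$power[abs(sp2$freq_bpm - f) <= sp2$bin_bpm + 1e-9])
  expect_gt(near(192), 3 * stats::median(sp2$power))
  expect_gt(near(96), near(192))

  expect_error(respiration_spectrum(sine_ts(1.6, 20, 5)), "10 s")
})
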