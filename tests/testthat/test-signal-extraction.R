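# Region tracking, gap handling, noise regressors, projection denoising,
# band-pass conditioning and gradient clipping.

test_that("region tracking: centroid, area and bounding box conventions", {
  m1 <- matrix(FALSE, 10, 10); m1[4, 8] <- TRUE        # pixel (3,7) 0-based
  m2 <- matrix(FALSE, 10, 10); m2[3:6, 3:6] <- TRUE    # 4x4 at rows/cols 2-5
  m3 <- matrix(FALSE, 10, 10)
  m3[1, 1] <- TRUE; m3[2, 1] <- TRUE; m3[2, 2] <- TRUE # L: (0,0),(1,0),(1,1)
  seq <- mask_sequence(list(m1, m2, m3), scores = rep(1, 3), fps = 1)
  tr <- track_region(gate_validity(seq, 0))

  expect_equal(tr$area, c(1, 16, 3))
  expect_equal(tr$com_y[1L], 3); expect_equal(tr$com_x[1L], 7)
  expect_equal(unname(tr$bbox[1L, ]), c(3L, 7L, 4L, 8L))
  expect_equal(tr$com_y[2L], 3.5); expect_equal(tr$com_x[2L], 3.5)
  expect_equal(tr$com_y[3L], 2 / 3 + 0)  # rows 0,1,1 -> mean 2/3
  expect_equal(tr$com_x[3L], 1 / 3)
  expect_error(track_region(gate_validity(seq, 1.1)), "invalid")
})

test_that("gap filling interpolates short gaps and splits on long ones", {
  mk <- function(area) { m <- matrix(FALSE, 2, 60); m[1:2, 1:(area / 2)] <- TRUE; m }
  masks <- list(mk(100), mk(100), mk(102))
  seq <- mask_sequence(masks, scores = c(1, 0.1, 1), fps = 2)
  tr <- fill_gaps(track_region(gate_validity(seq, 0.5)), max_gap_s = 0.5)
  expect_equal(tr$area[2L], 101)
  expect_true(all(tr$segment == 1L))

  # identity when nothing is invalid
  seq2 <- mask_sequence(masks, scores = rep(1, 3), fps = 2)
  tr2 <- fill_gaps(track_region(gate_validity(seq2, 0.5)))
  expect_equal(tr2$area, c(100, 100, 102))

  # long gap: two segments; lengths + gap = original length
  scores <- c(1, 1, 1, 0.1, 0.1, 0.1, 1, 1)
  masks8 <- lapply(c(100, 100, 100, 100, 100, 100, 102, 102), mk)
  seq3 <- mask_sequence(masks8, scores = scores, fps = 2)
  tr3 <- fill_gaps(track_region(gate_validity(seq3, 0.5)), max_gap_s = 1)
  segs <- split(seq_along(tr3$segment), tr3$segment)
  expect_length(segs, 2L)
  expect_equal(sum(lengths(segs)) + sum(is.na(tr3$segment)), 8L)
})

test_that("noise regressors are detrended and track the drift frequency", {
  n <- 600; fps <- 60
  t <- (seq_len(n) - 1) / fps
  mkd <- function(cx, cy) region_track(
    area = rep(100, n), com_x = cx, com_y = cy,
    bbox = matrix(0L, n, 4L), valid = rep(TRUE, n), fps = fps)

  # perfectly linear centroid -> all-zero regressors
  lin <- fill_gaps(mkd(1 + 0.01 * seq_len(n), rep(5, n)))
  q <- build_noise_subspace(lin)
  expect_lt(max(abs(q)), 1e-8)

  # every column carries no best-fit line
  f0 <- 0.7
  drift <- fill_gaps(mkd(5 + 3 * sin(2 * pi * f0 * t), 5 + t^1.5 / 100))
  q <- build_noise_subspace(drift)
  for (j in 1:4) {
    cf <- stats::lm.fit(cbind(1, seq_len(n)), q[, j])$coefficients
    expect_lt(max(abs(cf)), 1e-8)
  }
  # derivative of the sinusoidal drift keeps the drift frequency
  o <- dominant_freq(q[, "d_com_x"], fps)
  expect_lt(abs(o$freq - f0), o$bin + 1e-12)

  tiny <- region_track(area = c(1, 1), com_x = c(0, 1), com_y = c(0, 1),
                       bbox = matrix(0L, 2, 4L), valid = c(TRUE, TRUE),
                       fps = 1)
  expect_error(build_noise_subspace(fill_gaps(tiny)), "3 frames")
})

test_that("projection removes the noise subspace and nothing else", {
  set.seed(42)
  n <- 600
  r <- time_series(stats::rnorm(n), 60)

  # all-zero regressors: identity
  z0 <- denoise_projection(r, matrix(0, n, 4))
  expect_equal(z0$values, r$values)

  # signal inside the subspace vanishes
  q <- matrix(stats::rnorm(n * 4), n, 4)
  rin <- time_series(q[, 2L] * 3, 60)
  zin <- denoise_projection(rin, q)
  expect_lt(max(abs(zin$values)), 1e-8 * max(abs(rin$values)))

  # orthogonality and idempotence on random input
  z <- denoise_projection(r, q)
  resid <- crossprod(q, z$values)
  expect_lt(max(abs(resid)), 1e-8 * norm(q, "F") * sqrt(sum(r$values^2)))
  z2 <- denoise_projection(z, q)
  expect_equal(z2$values, z$values, tolerance = 1e-10)

  # rank-deficient regressors are tolerated
  qdef <- cbind(q[, 1L], q[, 1L] * 2, 0, 0)
  expect_silent(denoise_projection(r, qdef))

  expect_error(denoise_projection(r, matrix(0, 10, 2)), "length")
})

test_that("band-pass keeps the respiration band and rejects DC and drift", {
  fs <- 60
  # constant input -> ~0
  const <- time_series(rep(5, fs * 30), fs)
  expect_lt(max(abs(bandpass_respiration(const)$values)), 1e-6 * 5)

  # in-band tone survives with amplitude ~1 (zero-phase squared response)
  tone <- sine_ts(1.6, fs, 40)
  out <- bandpass_respiration(tone)
  mid <- out$values[(10 * fs):(30 * fs)]
  expect_gt(tone_amplitude(mid, fs, 1.6), 0.9)
  expect_lt(tone_amplitude(mid, fs, 1.6), 1.1)

  # far out-of-band drift is crushed
  slow <- sine_ts(0.2, fs, 40)
  outs <- bandpass_respiration(slow)
  expect_lt(tone_amplitude(outs$values[(10 * fs):(30 * fs)], fs, 0.2), 0.1)

  expect_error(bandpass_respiration(time_series(rnorm(30), fs)), "settled")
  expect_error(bandpass_respiration(time_series(rnorm(100), 5)), "too low")
})

test_that("band edges sit at the analytic zero-phase half-power gain", {
  fs <- 60
  for (f_edge in c(1, 3.3)) {
    tone <- sine_ts(f_edge, fs, 60)
    out <- bandpass_respiration(tone)
    amp <- tone_amplitude(out$values[(20 * fs):(40 * fs)], fs, f_edge)
    expect_equal(amp, 0.5, tolerance = 0.02)  # (1/sqrt(2))^2 forward+backward
  }
})

test_that("gradient clipping removes spikes and only spikes", {
  smooth <- time_series(sin(seq(0, 20, by = 0.1)) * 0.5, 10)
  expect_equal(clip_gradient(smooth, 1.5)$values, smooth$values)

  spike <- time_series(c(0, 0, 5, 0, 0), 10)
  expect_equal(clip_gradient(spike, 1.5)$values, rep(0, 5))

  ramp <- time_series(2 * (0:9), 10)
  expect_error(clip_gradient(ramp, 1.5), "every sample")

  # spike at the edge takes the nearest surviving value
  edge <- time_series(c(9, 0, 0, 0, 0), 10)
  expect_equal(clip_gradient(edge, 1.5)$values, rep(0, 5))
})

test_that("centroid alignment never changes the area signal", {
  gen <- generate_breathing_masks(small_blob(duration_s = 2,
                                             artifact_times = 1))
  seq <- gate_validity(gen$masks)
  tr <- track_region(seq)
  aligned <- align_masks_com(seq, tr)
  a1 <- vapply(seq$masks, sum, numeric(1L))
  a2 <- vapply(aligned$masks, sum, numeric(1L))
  expect_identical(a1, a2)
  # and alignment did move pixels
  expect_false(identical(seq$masks, aligned$masks))
})
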