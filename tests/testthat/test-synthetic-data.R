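# Ground-truth RR generator, synthetic PPG and synthetic face video.

test_that("constant-rate RR series is exact", {
  tr <- generate_rr_series(60, 60)
  expect_length(tr$nni, 60)
  expect_equal(tr$nni, rep(1000, 60), tolerance = 1e-9)
  expect_equal(max(abs(tr$nni - diff(tr$beat_times) * 1000)), 0, tolerance = 1e-9)

  tr72 <- generate_rr_series(600, 72)
  expect_equal(mean(tr72$nni), 60000 / 72, tolerance = 1e-9)
})

test_that("RR generator rejects non-physiological input", {
  expect_error(generate_rr_series(60, 25), "physiological")
  expect_error(generate_rr_series(60, 200), "physiological")
  expect_error(generate_rr_series(-1, 60), "duration_s")
  expect_error(generate_rr_series(60, 60, lf_amp = 0.6, hf_amp = 0.5), "< 1")
})

test_that("HF-only modulation places the spectral peak in the HF band", {
  tr <- generate_rr_series(600, 60, hf_amp = 0.05, hf_freq_hz = 0.25, seed = 1)
  # independent oracle: raw periodogram of the linearly resampled tachogram
  t <- tr$beat_times[-1]; y <- tr$nni
  grid <- seq(t[1], t[length(t)], by = 0.25)
  rs <- approx(t, y, xout = grid)$y
  sp <- spec.pgram(ts(rs - mean(rs), frequency = 4), plot = FALSE, taper = 0)
  peak_hz <- sp$freq[which.max(sp$spec)]
  expect_gte(peak_hz, 0.15)
  expect_lte(peak_hz, 0.4)
  # and the packaged Lomb-Scargle view agrees
  p <- psd_estimate(nni_from_times(tr$beat_times), "lomb")
  expect_gte(p$freqs[which.max(p$power)], 0.15)
  expect_lte(p$freqs[which.max(p$power)], 0.4)
})

test_that("RR generator is reproducible from its seed", {
  a <- generate_rr_series(120, 75, lf_amp = 0.04, hf_amp = 0.04,
                          jitter_sd_ms = 10, seed = 7)
  b <- generate_rr_series(120, 75, lf_amp = 0.04, hf_amp = 0.04,
                          jitter_sd_ms = 10, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$nni >= 300 & a$nni <= 2000))
  expect_true(all(diff(a$beat_times) > 0))
})

test_that("noiseless PPG has one maximum per beat, at the beat time", {
  tr <- generate_rr_series(60, 72, seed = 2)
  ppg <- synthesize_ppg(tr, fs_hz = 100, noise_sd = 0)
  mx <- naive_local_maxima(ppg$values)
  mx <- mx[ppg$values[mx] > 0.5]
  expect_length(mx, length(tr$beat_times))
  peak_t <- (mx - 1) / ppg$fs
  expect_lte(max(abs(peak_t - tr$beat_times)), 1 / ppg$fs)
})

test_that("PPG synthesis validates its inputs", {
  tr <- generate_rr_series(30, 60)
  empty <- tr; empty$beat_times <- numeric(0)
  expect_error(synthesize_ppg(empty), "no beats")
  expect_error(synthesize_ppg(tr, fs_hz = 10), ">= 25")
  expect_error(synthesize_ppg(tr, pulse_width_s = 2), "shortest")
})

test_that("video frame count equals fps times duration", {
  tr <- generate_rr_series(600, 60)
  st <- synthesize_face_video(tr, fps = 30, width = 16, height = 16,
                              roi = roi_box(4, 4, 8, 8))
  expect_identical(n_frames <- dim(st$video$frames)[4], 18000L)
})

test_that("ROI red mean oscillates at the pulse frequency", {
  st <- tiny_study(duration_s = 60, hr = 72, seed = 3)
  cropped <- crop_to_roi(st$video, fixed_track(st$video, st$roi_truth))
  v <- channel_mean_signal(cropped, "R")$values
  v <- v - mean(v)
  sp <- spec.pgram(ts(v, frequency = 30), plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 72 / 60, tolerance = 0.05)
})

test_that("video generator enforces its preconditions", {
  tr <- generate_rr_series(10, 60)
  expect_error(synthesize_face_video(tr, width = 16, height = 16,
                                     roi = roi_box(10, 10, 10, 10)), "outside")
  expect_error(synthesize_face_video(tr, modulation_depth = 0), "0, 0.1")
  expect_error(synthesize_face_video(tr, modulation_depth = 0.5), "0, 0.1")
})

test_that("round-trip at zero noise recovers beats with precision and recall 1", {
  tr <- generate_rr_series(120, 65, lf_amp = 0.03, hf_amp = 0.05, seed = 4)
  ppg <- synthesize_ppg(tr, fs_hz = 100, noise_sd = 0)
  train <- detect_peaks(preprocess_signal(ppg))
  m <- match_peaks(train$times, tr$beat_times, tolerance_s = 0.05)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
})

test_that("paired study is seed-deterministic and internally consistent", {
  a <- simulate_study(duration_s = 20, width = 16, height = 16, seed = 11)
  b <- simulate_study(duration_s = 20, width = 16, height = 16, seed = 11)
  expect_identical(a$ppg$values, b$ppg$values)
  expect_identical(a$video$frames, b$video$frames)
  # durations agree with the truth within one beat
  dur <- max(a$truth$beat_times)
  expect_lt(abs(signal_dur <- length(a$ppg$values) / a$ppg$fs - dur), max(a$truth$nni) / 1000)
  expect_lt(abs(dim(a$video$frames)[4] / a$fps - dur), max(a$truth$nni) / 1000)
})

test_that("HF-only modulation yields more relative HF than LF power", {
  tr <- generate_rr_series(300, 70, hf_amp = 0.05, hf_freq_hz = 0.3, seed = 5)
  nni <- nni_from_times(tr$beat_times)
  b <- band_features(psd_estimate(nni, "welch"))
  expect_gt(b[["welch_hf_rel"]], b[["welch_lf_rel"]])
})

test_that("a synthetic study writes and reloads from disk", {
  st <- simulate_study(duration_s = 5, width = 8, height = 8,
                       roi = roi_box(2, 2, 4, 4), seed = 6,
                       video_noise_sd = 0, ppg_noise_sd = 0)
  dir <- withr::local_tempdir()
  write_synth_study(st, dir)
  expect_true(file.exists(file.path(dir, "ppg.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  ppg <- read_ppg_csv(file.path(dir, "ppg.csv"))
  expect_equal(ppg$values, st$ppg$values)
  expect_equal(ppg$fs, st$ppg$fs, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$beat_times, st$truth$beat_times, tolerance = 1e-9)
})
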