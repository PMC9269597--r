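# HRV feature catalogue: time-domain, frequency-domain, non-linear.

test_that("time-domain features of a constant series are exact", {
  nni <- nni_from_times(cumsum(c(0, rep(1, 61))))
  f <- time_domain_features(nni)
  expect_equal(f[["nni_mean"]], 1000)
  expect_equal(f[["sdnn"]], 0)
  expect_equal(f[["rmssd"]], 0)
  expect_equal(f[["nn50"]], 0)
  expect_equal(f[["pnn50"]], 0)
  expect_equal(f[["hr_mean"]], 60)
  expect_length(f, 15)
})

test_that("time-domain features match hand-evaluated formulas", {
  f <- time_domain_features(nni_series(c(1000, 950, 1050), c(1, 1.95, 3)))
  expect_equal(f[["rmssd"]], sqrt((50^2 + 100^2) / 2), tolerance = 1e-9)
  expect_equal(f[["nn50"]], 1)           # only |+100| > 50, strict
  expect_equal(f[["pnn50"]], 50)
  expect_equal(f[["sdsd"]], sd(c(-50, 100)))
  expect_equal(f[["nni_diff_mean"]], 75)
  expect_error(time_domain_features(nni_series(c(1000, 900), c(1, 1.9))), "too few")
})

test_that("time-domain dispersion features scale with the intervals", {
  set.seed(2)
  x <- 900 + rnorm(100, sd = 40)
  a <- time_domain_features(nni_series(x, cumsum(x) / 1000))
  b <- time_domain_features(nni_series(2 * x, cumsum(2 * x) / 1000))
  for (nm in c("nni_mean", "sdnn", "rmssd", "sdsd"))
    expect_equal(b[[nm]], 2 * a[[nm]], tolerance = 1e-9)
})

test_that("resampling the tachogram preserves constants and tones", {
  const <- nni_series(rep(800, 20), cumsum(rep(0.8, 20)))
  rs <- resample_nni(const, 4)
  expect_true(all(abs(rs$values - 800) < 1e-6))
  expect_equal(rs$fs, 4)

  tr <- generate_rr_series(300, 70, lf_amp = 0.05, lf_freq_hz = 0.1, seed = 3)
  rs <- resample_nni(nni_from_times(tr$beat_times), 4)
  sp <- spec.pgram(ts(rs$values - mean(rs$values), frequency = 4),
                   plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 0.1, tolerance = 0.02)

  expect_warning(resample_nni(nni_series(c(800, 820, 810), c(1, 1.8, 2.6))),
                 "linear")
})

test_that("all three spectral estimators recover a single tone within one bin", {
  tr <- generate_rr_series(600, 70, hf_amp = 0.05, hf_freq_hz = 0.25, seed = 4)
  nni <- nni_from_times(tr$beat_times)
  for (method in c("welch", "ar", "lomb")) {
    p <- psd_estimate(nni, method)
    fpeak <- p$freqs[which.max(p$power)]
    bin <- max(diff(p$freqs)[1], 1e-4)
    expect_lte(abs(fpeak - 0.25), bin + 1e-9)
  }
})

test_that("Welch total power satisfies Parseval within 10%", {
  set.seed(5)
  x <- 900 + rnorm(240, sd = 30)  # white-jitter nni, 1 min at 4 Hz
  nni <- nni_series(x, cumsum(x) / 1000)
  rs <- resample_nni(nni, 4)
  p <- psd_estimate(nni, "welch", list(seg_len = 128L))
  total <- trapz(p$freqs, p$power)
  expect_equal(total, var(rs$values), tolerance = 0.1)
})

test_that("Burg AR recovers the spectral peak of an AR(2) tachogram", {
  # AR(2) with a resonance at f0 cycles/beat: x_t = a1 x_{t-1} + a2 x_{t-2} + e_t
  rho <- 0.95; f0 <- 0.2
  a1 <- 2 * rho * cos(2 * pi * f0); a2 <- -rho^2
  set.seed(6)
  x <- as.numeric(stats::arima.sim(list(ar = c(a1, a2)), 2048)) * 10 + 900
  nni <- nni_series(pmax(x, 300), cumsum(pmax(x, 300)) / 1000)
  p <- psd_estimate(nni, "ar", list(order = 2L))
  fpeak <- p$freqs[which.max(p$power)]
  # 0.2 cycles/beat maps to Hz through the mean beat interval
  expected_hz <- f0 / (mean(nni$nni) / 1000)
  expect_equal(fpeak, expected_hz, tolerance = 0.1)
})

test_that("band features: 12 per method, relative powers sum to one", {
  tr <- generate_rr_series(600, 65, hf_amp = 0.05, hf_freq_hz = 0.25, seed = 7)
  nni <- nni_from_times(tr$beat_times)
  for (method in c("welch", "ar", "lomb")) {
    b <- band_features(psd_estimate(nni, method))
    expect_length(b, 12)
    rel <- b[grep("_rel$", names(b))]
    expect_equal(sum(rel), 1, tolerance = 1e-6)
    expect_gt(b[[paste0(method, "_hf_rel")]], 0.8)
    expect_equal(b[[paste0(method, "_hf_peak")]], 0.25, tolerance = 0.01)
  }
})

test_that("LF:HF power ratio 1:2 is recovered by all three estimators", {
  tr <- generate_rr_series(600, 70, lf_amp = 0.03, lf_freq_hz = 0.1,
                           hf_amp = 0.03 * sqrt(2), hf_freq_hz = 0.25, seed = 5)
  nni <- nni_from_times(tr$beat_times)
  for (method in c("welch", "ar", "lomb")) {
    b <- band_features(psd_estimate(nni, method))
    ratio <- b[[paste0(method, "_hf_rel")]] / b[[paste0(method, "_lf_rel")]]
    expect_gte(ratio, 1.5)
    expect_lte(ratio, 2.7)
  }
})

test_that("Poincare features follow the rotation-of-axes construction", {
  const <- rep(1000, 10)
  pc <- poincare_features(nni_series(const, cumsum(const) / 1000))
  expect_equal(unname(pc[c("sd1", "sd2", "ellipse_area")]), c(0, 0, 0))

  alt <- rep(c(900, 1100), 25)
  pc <- poincare_features(alt)
  expect_equal(pc[["sd1"]], sd(diff(alt)) / sqrt(2), tolerance = 1e-9)
  expect_equal(pc[["sd1"]], 200 / sqrt(2), tolerance = 0.02)  # ~ 141.42 ms

  # oracle equivalence: SD1 equals the SD of the rotated coordinate (x-y)/sqrt(2)
  set.seed(8)
  x <- 900 + rnorm(200, sd = 50)
  rot <- (x[-length(x)] - x[-1]) / sqrt(2)
  expect_equal(poincare_features(x)[["sd1"]], sd(rot), tolerance = 1e-9)
})

test_that("sample entropy matches the naive O(N^2) counter and behaves", {
  per <- rep(c(900, 1000, 1100), 40)
  expect_lt(sample_entropy(per), 0.05)

  set.seed(9)
  x <- 900 + 100 * sin(2 * pi * (1:200) / 10) + rnorm(200, sd = 15)
  expect_equal(sample_entropy(x), naive_sampen(x), tolerance = 1e-12)

  shuffled <- sample(x)
  expect_gte(sample_entropy(shuffled), sample_entropy(x))
})

test_that("DFA separates white noise from integrated noise", {
  set.seed(10)
  white <- 1000 + rnorm(3000, sd = 30)
  expect_equal(dfa(white)$alpha_overall, 0.5, tolerance = 0.1)
  walk <- 1000 + cumsum(rnorm(3000, sd = 5))
  expect_equal(dfa(walk)$alpha_overall, 1.5, tolerance = 0.1)
  # fluctuation grows across dyadic scales
  d <- dfa(white, short_scales = 2^(2:4), long_scales = 2^(4:6))
  expect_true(all(diff(d$fluctuation) >= 0))
})

test_that("the full catalogue has 15 + 36 + 12 = 63 deterministic entries", {
  cat_df <- hrv_catalog()
  counts <- table(cat_df$method_tag)
  expect_equal(unname(counts[["time"]]), 15)
  expect_equal(sum(counts[grep("^freq_", names(counts))]), 36)
  expect_equal(unname(counts[["nonlinear"]]), 12)
  expect_equal(nrow(cat_df), 63)

  tr <- generate_rr_series(600, 70, lf_amp = 0.04, hf_amp = 0.04,
                           jitter_sd_ms = 10, seed = 11)
  f <- extract_all_features(nni_from_times(tr$beat_times))
  expect_equal(f$name, cat_df$name)
  expect_true(all(is.finite(f$value) | f$missing))
})

test_that("families that cannot be computed are flagged missing, not fatal", {
  short <- nni_series(c(800, 820, 810, 805, 815), cumsum(c(800, 820, 810, 805, 815)) / 1000)
  expect_warning(f <- extract_all_features(short), "incomplete")
  expect_true(any(f$missing))                # welch needs a full segment
  expect_false(any(f$missing[f$method_tag == "time"]))
  expect_error(extract_all_features(short, strict = TRUE), "failed")
})
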