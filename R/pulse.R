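# Pulse extraction: turn a cropped (optionally magnified) clip or a PPG trace
# into a peak train and NN-interval series, and compute heart rates.

#' Construct a uniformly sampled signal
#'
#' @param values Numeric amplitude vector (length >= 1).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `pulse_signal`.
#' @export
pulse_signal <- function(values, fs, t0 = 0) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  stop_if_not_scalar_pos(fs, "fs")
  structure(list(values = as.numeric(values), fs = fs, t0 = t0),
            class = "pulse_signal")
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("<pulse_signal> %d samples @ %g Hz (%.1f s from t0=%.2f)\n",
              length(x$values), x$fs, length(x$values) / x$fs, x$t0))
  invisible(x)
}

signal_duration_s <- function(sig) length(sig$values) / sig$fs

#' Spatial channel mean of a frame stack
#'
#' `value[t]` is the spatial mean of the chosen colour channel of frame `t`;
#' for rPPG the red channel carries the pulse. The result is sampled at the
#' frame rate.
#'
#' @param frames A [frame_stack()].
#' @param channel One of `"R"`, `"G"`, `"B"` (per the stack's declared order).
#' @return A [pulse_signal()] with `fs = fps`.
#' @export
channel_mean_signal <- function(frames, channel = "R") {
  stopifnot(inherits(frames, "frame_stack"))
  idx <- match(channel, strsplit(frames$channels, "")[[1L]])
  if (is.na(idx)) stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  d <- dim(frames$frames)
  plane <- frames$frames[, , idx, , drop = FALSE]
  v <- colMeans(matrix(plane, d[1L] * d[2L], d[4L]))
  pulse_signal(v, fs = frames$fps, t0 = frames$t0)
}

#' Detrend and bandpass a pulse signal
#'
#' Removes the best-fit linear trend, then applies the ideal FFT bandpass of
#' [temporal_ideal_bandpass()] over the heart band. Length and sampling rate
#' are preserved; a constant input maps to all zeros.
#'
#' @param sig A [pulse_signal()].
#' @param band Passband `c(f_lo, f_hi)` in Hz; default 0.67-3 Hz
#'   (40-180 bpm).
#' @return A zero-mean filtered [pulse_signal()].
#' @export
preprocess_signal <- function(sig, band = c(0.67, 3)) {
  stopifnot(inherits(sig, "pulse_signal"))
  v <- sig$values
  n <- length(v)
  if (n < 4L || (band[1L] > 0 && n / sig$fs < 2 / band[1L]))
    stop("signal too short for the requested passband", call. = FALSE)
  tt <- seq_len(n)
  slope <- stats::cov(tt, v) / stats::var(tt)
  v <- v - (mean(v) + slope * (tt - mean(tt)))
  filt <- temporal_ideal_bandpass(v, sig$fs, band[1L], band[2L])
  pulse_signal(filt, fs = sig$fs, t0 = sig$t0)
}

#' Construct a peak train
#'
#' @param indices Strictly increasing 1-based sample indices of peaks.
#' @param fs Sampling rate of the source signal (Hz).
#' @param t0 Start time of the source signal (s).
#' @param duration_s Duration of the source signal (s); retained so that
#'   count-based heart rates and alignment have a well-defined window.
#' @return An object of class `peak_train` with `indices` and `times`.
#' @export
peak_train <- function(indices, fs, t0 = 0, duration_s = NULL) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("peak indices must be strictly increasing", call. = FALSE)
  structure(list(indices = indices, times = t0 + (indices - 1L) / fs,
                 fs = fs, t0 = t0,
                 duration_s = duration_s %||% NA_real_),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train> %d peaks over %.1f s\n", length(x$indices), x$duration_s))
  invisible(x)
}

#' Detect systolic peaks in a preprocessed pulse signal
#'
#' Keeps local maxima that (i) clear a height threshold of `mean + k * sd` of
#' the signal and (ii) are separated by at least `min_distance_s`; when two
#' candidates conflict the higher one wins. The defaults encode physiology:
#' 0.33 s spacing corresponds to a 180 bpm ceiling, and `k = 0.5` is
#' permissive enough for amplitude-modulated rPPG while rejecting baseline
#' ripple.
#'
#' @param sig A (preprocessed, near-zero-mean) [pulse_signal()].
#' @param min_distance_s Minimum spacing between retained peaks in seconds.
#' @param height_k Threshold multiplier `k` in `mean + k * sd`.
#' @return A [peak_train()]; empty when nothing clears the threshold.
#' @export
detect_peaks <- function(sig, min_distance_s = 0.33, height_k = 0.5) {
  stopifnot(inherits(sig, "pulse_signal"))
  stop_if_not_scalar_pos(min_distance_s, "min_distance_s")
  v <- sig$values
  n <- length(v)
  if (n < 3L) return(peak_train(integer(0), sig$fs, sig$t0, signal_duration_s(sig)))
  sdv <- stats::sd(v)
  thr <- mean(v) + height_k * sdv
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  if (v[1L] > v[2L]) cand <- c(1L, cand)        # boundary samples can be peaks
  if (v[n] > v[n - 1L]) cand <- c(cand, n)
  cand <- cand[v[cand] >= thr]
  if (sdv == 0) cand <- integer(0)  # flat signal has no peaks
  if (length(cand) > 1L) {
    min_gap <- min_distance_s * sig$fs
    ord <- cand[order(v[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  peak_train(cand, sig$fs, sig$t0, signal_duration_s(sig))
}

#' Construct an NN-interval series
#'
#' @param nni Successive inter-beat intervals in ms (all > 0).
#' @param t Interval end times in seconds (one per interval, strictly
#'   increasing); used by the Lomb-Scargle estimator and for resampling.
#' @param beat_times Full vector of beat times when the series is contiguous
#'   (i.e. `nni == diff(beat_times) * 1000`); `NULL` after intervals have
#'   been filtered out.
#' @return An object of class `nni_series`.
#' @export
nni_series <- function(nni, t, beat_times = NULL) {
  if (length(nni) != length(t)) stop("nni and t must have equal length", call. = FALSE)
  if (any(nni <= 0)) stop("all NN intervals must be positive", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) stop("interval times must be strictly increasing", call. = FALSE)
  if (!is.null(beat_times)) {
    if (length(beat_times) != length(nni) + 1L ||
        max(abs(diff(beat_times) * 1000 - nni)) > 1e-9)
      stop("beat_times inconsistent with nni", call. = FALSE)
  }
  structure(list(nni = as.numeric(nni), t = as.numeric(t), beat_times = beat_times),
            class = "nni_series")
}

#' @export
print.nni_series <- function(x, ...) {
  cat(sprintf("<nni_series> %d intervals, mean %.1f ms (%.1f bpm)%s\n",
              length(x$nni), mean(x$nni), 60000 / mean(x$nni),
              if (is.null(x$beat_times)) " [gapped]" else ""))
  invisible(x)
}

#' NN-interval series from beat times
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @return An [nni_series()] with `nni = diff(beat_times) * 1000`.
#' @export
nni_from_times <- function(beat_times) {
  if (length(beat_times) < 2L) stop("need at least 2 beats", call. = FALSE)
  nni_series(diff(beat_times) * 1000, beat_times[-1L], beat_times = beat_times)
}

#' Convert a peak train to NN intervals with plausibility filtering
#'
#' Successive peak-to-peak intervals become NN intervals. Implausibly short
#' intervals (< 300 ms, spurious double detections) are resolved by dropping
#' the later peak of the pair; implausibly long intervals (> 2000 ms, missed
#' beats) are dropped from the series as gaps without merging their
#' neighbours. When nothing is filtered the full beat-time vector is
#' retained, so `cumsum` reconstructs it exactly.
#'
#' @param train A [peak_train()] with at least 2 peaks.
#' @param plausible_ms Plausibility window in ms, default `c(300, 2000)`.
#' @return An [nni_series()].
#' @export
peaks_to_nni <- function(train, plausible_ms = c(NNI_MIN_MS, NNI_MAX_MS)) {
  stopifnot(inherits(train, "peak_train"))
  times <- train$times
  if (length(times) < 2L) stop("need at least 2 peaks to form intervals", call. = FALSE)
  repeat {
    d <- diff(times) * 1000
    short <- which(d < plausible_ms[1L])
    if (!length(short)) break
    times <- times[-(short[1L] + 1L)]
    if (length(times) < 2L) stop("all intervals implausibly short", call. = FALSE)
  }
  d <- diff(times) * 1000
  keep <- d <= plausible_ms[2L]
  if (!any(keep)) stop("no plausible NN intervals remain", call. = FALSE)
  nni_series(d[keep], times[-1L][keep],
             beat_times = if (all(keep)) times else NULL)
}

#' Count-based mean heart rate
#'
#' `60 * n_peaks / duration_s` — the heart-rate definition used for the
#' error-metric comparison between branches (as opposed to the HRV feature
#' `hr_mean`, the mean of `60000 / nni`).
#'
#' @param train A [peak_train()].
#' @param duration_s Observation window in seconds (defaults to the train's
#'   recorded source duration).
#' @return Heart rate in bpm.
#' @export
mean_heart_rate <- function(train, duration_s = train$duration_s) {
  stopifnot(inherits(train, "peak_train"))
  stop_if_not_scalar_pos(duration_s, "duration_s")
  60 * length(train$indices) / duration_s
}

#' Per-minute heart rate from a peak train
#'
#' Counts peaks in consecutive full 60 s windows aligned to the train's start
#' time (a count per 60 s window is itself a bpm value); the trailing partial
#' window is discarded.
#'
#' @param train A [peak_train()].
#' @param total_duration_s Total observation time in seconds (>= 60).
#' @return Numeric vector with one bpm value per full minute.
#' @export
per_minute_heart_rate <- function(train, total_duration_s = train$duration_s) {
  stopifnot(inherits(train, "peak_train"))
  if (!is.finite(total_duration_s) || total_duration_s < 60)
    stop("need at least 60 s for a per-minute stratification", call. = FALSE)
  nwin <- floor(total_duration_s / 60)
  rel <- train$times - train$t0
  vapply(seq_len(nwin) - 1L,
         function(k) sum(rel >= 60 * k & rel < 60 * (k + 1)), numeric(1L))
}

#' Read a PPG waveform from a two-column CSV
#'
#' Expects columns `time_s, amplitude`; the sampling rate is taken from the
#' median time step (or can be forced with `fs`).
#'
#' @param path CSV file path.
#' @param fs Optional sampling rate override in Hz.
#' @return A [pulse_signal()].
#' @export
read_ppg_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected columns time_s, amplitude", call. = FALSE)
  fs <- fs %||% (1 / stats::median(diff(d[[1L]])))
  pulse_signal(d[[2L]], fs = fs, t0 = d[[1L]][1L])
}

#' Write a pulse signal as a two-column CSV
#'
#' @param sig A [pulse_signal()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(sig, path) {
  stopifnot(inherits(sig, "pulse_signal"))
  t <- sig$t0 + (seq_along(sig$values) - 1L) / sig$fs
  utils::write.csv(data.frame(time_s = t, amplitude = sig$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Match detected peaks to ground-truth beats
#'
#' Greedy in-order one-to-one matching: walking both sorted sequences, a
#' detection is matched to the closest unused truth beat within
#' `tolerance_s`. Returns precision (matched / detected), recall
#' (matched / truth) and the match count.
#'
#' @param detected_times Detected peak times in seconds (sorted).
#' @param truth_times Ground-truth beat times in seconds (sorted).
#' @param tolerance_s Matching tolerance in seconds (default 0.05 = +/-50 ms).
#' @return List with `n_matched`, `n_detected`, `n_truth`, `precision`,
#'   `recall`.
#' @export
match_peaks <- function(detected_times, truth_times, tolerance_s = 0.05) {
  nd <- length(detected_times); ntr <- length(truth_times)
  used <- logical(ntr)
  matched <- 0L
  j <- 1L
  for (d in detected_times) {
    while (j <= ntr && truth_times[j] < d - tolerance_s) j <- j + 1L
    best <- NA_integer_; bestd <- Inf
    k <- j
    while (k <= ntr && truth_times[k] <= d + tolerance_s) {
      if (!used[k] && abs(truth_times[k] - d) < bestd) {
        best <- k; bestd <- abs(truth_times[k] - d)
      }
      k <- k + 1L
    }
    if (!is.na(best)) { used[best] <- TRUE; matched <- matched + 1L }
  }
  list(n_matched = matched, n_detected = nd, n_truth = ntr,
       precision = if (nd) matched / nd else NA_real_,
       recall = if (ntr) matched / ntr else NA_real_)
}
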