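# Synthetic-data module: ground-truth RR series, pulse-shaped PPG traces and
# skin-patch videos with a pulse-synchronous red-channel modulation. These
# emulate the paired pulse-oximeter + camera recording the pipeline expects,
# with known beat times, so every downstream stage can be tested against
# ground truth.

# Physiological plausibility window for NN intervals (ms), shared with the
# peak-to-NNI filtering stage.
NNI_MIN_MS <- 300
NNI_MAX_MS <- 2000

#' Generate a ground-truth RR interval series
#'
#' Beats are produced by integral pulse frequency modulation (IPFM): an
#' instantaneous rate
#' \deqn{r(t) = r_0 (1 + a_{LF} \sin 2\pi f_{LF} t + a_{HF} \sin 2\pi f_{HF} t)}
#' with \eqn{r_0} the mean beat rate in Hz is integrated, and a beat fires
#' every time the integral crosses an integer. Sinusoidal rate modulation
#' inside the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands gives the NN
#' series controllable spectral band powers, mimicking sympathetic and
#' parasympathetic (respiratory sinus arrhythmia) modulation. Optional white
#' Gaussian jitter is added to the beat times afterwards.
#'
#' @param duration_s Length of the recording in seconds (> 0).
#' @param mean_hr_bpm Mean heart rate, beats per minute, in `[30, 180]`.
#' @param lf_amp,hf_amp Fractional rate-modulation amplitudes (>= 0);
#'   `lf_amp + hf_amp` must stay below 1 so the rate is always positive.
#' @param lf_freq_hz,hf_freq_hz Modulation frequencies in Hz, conventionally
#'   inside the LF and HF bands.
#' @param jitter_sd_ms Standard deviation of i.i.d. Gaussian beat-time jitter
#'   in milliseconds.
#' @param seed Optional integer seed; identical arguments and seed give
#'   bit-identical output, and the caller's RNG state is left untouched.
#' @return An object of class `rr_truth` with `beat_times` (seconds, strictly
#'   increasing, starting at 0), `nni` (successive intervals in ms, clamped
#'   to the physiological window 300-2000 ms) and `params`.
#' @export
generate_rr_series <- function(duration_s, mean_hr_bpm,
                               lf_amp = 0, lf_freq_hz = 0.1,
                               hf_amp = 0, hf_freq_hz = 0.25,
                               jitter_sd_ms = 0, seed = NULL) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  if (!is.numeric(mean_hr_bpm) || length(mean_hr_bpm) != 1L ||
      mean_hr_bpm < 30 || mean_hr_bpm > 180)
    stop("mean_hr_bpm outside the physiological range [30, 180] bpm", call. = FALSE)
  if (lf_amp < 0 || hf_amp < 0) stop("modulation amplitudes must be >= 0", call. = FALSE)
  if (lf_amp + hf_amp >= 1) stop("combined modulation amplitude must be < 1", call. = FALSE)
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be >= 0", call. = FALSE)
  r0 <- mean_hr_bpm / 60

  if (lf_amp == 0 && hf_amp == 0) {
    # analytic inversion of the constant-rate integral
    beat_times <- (0:floor(duration_s * r0)) / r0
  } else {
    # closed-form integral of r(t), inverted by interpolation on a 1 ms grid
    tg <- seq(0, duration_s, by = 0.001)
    Rt <- r0 * tg
    if (lf_amp > 0) {
      stop_if_not_scalar_pos(lf_freq_hz, "lf_freq_hz")
      Rt <- Rt + r0 * lf_amp * (1 - cos(2 * pi * lf_freq_hz * tg)) / (2 * pi * lf_freq_hz)
    }
    if (hf_amp > 0) {
      stop_if_not_scalar_pos(hf_freq_hz, "hf_freq_hz")
      Rt <- Rt + r0 * hf_amp * (1 - cos(2 * pi * hf_freq_hz * tg)) / (2 * pi * hf_freq_hz)
    }
    beat_times <- stats::approx(x = Rt, y = tg, xout = 0:floor(Rt[length(Rt)]))$y
  }

  if (jitter_sd_ms > 0) {
    beat_times <- with_seed(seed, {
      bt <- beat_times
      bt[-1L] <- bt[-1L] + stats::rnorm(length(bt) - 1L, sd = jitter_sd_ms / 1000)
      sort(bt)
    })
  }

  nni <- diff(beat_times) * 1000
  if (any(nni < NNI_MIN_MS | nni > NNI_MAX_MS)) {
    nni <- pmin(pmax(nni, NNI_MIN_MS), NNI_MAX_MS)
    beat_times <- beat_times[1L] + c(0, cumsum(nni)) / 1000
  }

  structure(list(
    beat_times = beat_times,
    nni = nni,
    params = list(duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
                  lf_amp = lf_amp, lf_freq_hz = lf_freq_hz,
                  hf_amp = hf_amp, hf_freq_hz = hf_freq_hz,
                  jitter_sd_ms = jitter_sd_ms, seed = seed)
  ), class = "rr_truth")
}

#' @export
print.rr_truth <- function(x, ...) {
  cat(sprintf("<rr_truth> %d beats over %.1f s (mean NN %.1f ms, %.1f bpm)\n",
              length(x$beat_times), max(x$beat_times),
              mean(x$nni), 60000 / mean(x$nni)))
  invisible(x)
}

# Evaluate a unit-amplitude Gaussian pulse train at times `t` (seconds),
# one bump of width `sigma_s` per beat. Only the +/- 5 sigma neighbourhood of
# each beat is touched, so the cost is O(beats * sigma * fs).
gaussian_pulse_train <- function(t, beat_times, sigma_s) {
  v <- numeric(length(t))
  if (length(t) < 2L) return(v)
  dt <- t[2L] - t[1L]
  halfwin <- ceiling(5 * sigma_s / dt)
  for (b in beat_times) {
    i0 <- max(1L, floor((b - t[1L]) / dt) - halfwin)
    i1 <- min(length(t), ceiling((b - t[1L]) / dt) + halfwin)
    if (i0 > i1) next
    idx <- i0:i1
    v[idx] <- v[idx] + exp(-((t[idx] - b)^2) / (2 * sigma_s^2))
  }
  v
}

#' Synthesize a photoplethysmogram from a ground-truth RR series
#'
#' Emulates a pulse-oximeter waveform: one unit-amplitude Gaussian bump per
#' heartbeat, centred on the ground-truth beat time, plus additive white
#' Gaussian noise. The Gaussian template matches the near-Gaussian pulse
#' shape the peak detector is designed for.
#'
#' @param truth An [generate_rr_series()] result.
#' @param fs_hz Sampling rate in Hz (>= 25).
#' @param pulse_width_s Gaussian sigma of one pulse in seconds; must be
#'   smaller than the shortest NN interval so pulses remain separable.
#' @param noise_sd Noise standard deviation as a fraction of the (unit)
#'   pulse amplitude.
#' @param seed Optional integer seed for the noise.
#' @return A [pulse_signal()] sampled on `[0, max(beat_times)]` at `fs_hz`.
#' @export
synthesize_ppg <- function(truth, fs_hz = 100, pulse_width_s = 0.05,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "rr_truth"))
  if (length(truth$beat_times) == 0L) stop("truth contains no beats", call. = FALSE)
  if (fs_hz < 25) stop("fs_hz must be >= 25 Hz", call. = FALSE)
  if (length(truth$nni) > 0L && pulse_width_s >= min(truth$nni) / 1000)
    stop("pulse_width_s must be smaller than the shortest NN interval", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  duration <- max(truth$beat_times)
  n <- floor(duration * fs_hz) + 1L
  t <- (seq_len(n) - 1L) / fs_hz
  v <- gaussian_pulse_train(t, truth$beat_times, pulse_width_s)
  if (noise_sd > 0) v <- v + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  pulse_signal(v, fs = fs_hz, t0 = 0)
}

#' Synthesize a facial video with a pulse-synchronous skin modulation
#'
#' Renders a static mid-gray background with a uniform skin-tone rectangle in
#' `roi`. Inside the ROI the red channel is `baseline * (1 + modulation_depth
#' * pulse(t))`, where `pulse(t)` is the unit Gaussian pulse train of the
#' ground-truth beats sampled at the frame times, plus optional per-pixel
#' Gaussian noise; the green and blue channels are static. Frames are floats,
#' so a 1% modulation (sub-quantum at 8 bits) stays representable; quantize
#' explicitly via [write_frames()] when 8-bit output is wanted.
#'
#' @param truth An [generate_rr_series()] result.
#' @param fps Frame rate in Hz.
#' @param width,height Frame size in pixels.
#' @param roi A [roi_box()] for the skin patch; must lie inside the frame.
#' @param modulation_depth Relative red-channel modulation depth in
#'   `(0, 0.1]`.
#' @param noise_sd Per-pixel Gaussian noise sd added to the red channel
#'   inside the ROI.
#' @param seed Optional integer seed.
#' @param skin_rgb Skin-tone base colour (RGB in `[0, 1]`).
#' @param background Background gray level.
#' @return A `synth_study` object whose `video` is the [frame_stack()]
#'   (`ppg` is `NULL`; see [simulate_study()] for a full paired study).
#' @export
synthesize_face_video <- function(truth, fps = 30, width = 64, height = 64,
                                  roi = roi_box(width %/% 4, height %/% 4,
                                                width %/% 2, height %/% 2),
                                  modulation_depth = 0.01, noise_sd = 0,
                                  seed = NULL,
                                  skin_rgb = c(0.80, 0.55, 0.45),
                                  background = 0.5) {
  stopifnot(inherits(truth, "rr_truth"))
  if (length(truth$beat_times) == 0L) stop("truth contains no beats", call. = FALSE)
  if (!is.numeric(modulation_depth) || modulation_depth <= 0 || modulation_depth > 0.1)
    stop("modulation_depth must lie in (0, 0.1]", call. = FALSE)
  if (!roi_inside_frame(roi, height, width))
    stop("roi lies outside the frame bounds", call. = FALSE)
  duration <- max(truth$beat_times)
  nt <- round(fps * duration)
  if (nt < 1L) stop("duration too short for a single frame", call. = FALSE)
  t <- (seq_len(nt) - 1L) / fps
  pulse <- gaussian_pulse_train(t, truth$beat_times, 0.05)

  arr <- array(background, dim = c(height, width, 3L, nt))
  ry <- roi_rows(roi); rx <- roi_cols(roi)
  npx <- length(ry) * length(rx)
  arr[ry, rx, 2L, ] <- skin_rgb[2L]
  arr[ry, rx, 3L, ] <- skin_rgb[3L]
  red <- rep(skin_rgb[1L] * (1 + modulation_depth * pulse), each = npx)
  if (noise_sd > 0) red <- red + with_seed(seed, stats::rnorm(length(red), sd = noise_sd))
  arr[ry, rx, 1L, ] <- red

  synth_study(truth = truth, ppg = NULL,
              video = frame_stack(arr, fps = fps),
              roi_truth = roi, fps = fps, ppg_fs = NULL)
}

#' Bundle a paired synthetic study
#'
#' @param truth Ground-truth RR series.
#' @param ppg PPG [pulse_signal()] or `NULL`.
#' @param video Video [frame_stack()] or `NULL`.
#' @param roi_truth The skin-patch [roi_box()].
#' @param fps,ppg_fs Sampling rates of the two branches.
#' @return An object of class `synth_study`.
#' @export
synth_study <- function(truth, ppg, video, roi_truth, fps, ppg_fs) {
  if (!is.null(video) && !is.null(roi_truth)) {
    d <- dim(video$frames)
    if (!roi_inside_frame(roi_truth, d[1L], d[2L]))
      stop("roi_truth lies outside the video frame", call. = FALSE)
  }
  structure(list(truth = truth, ppg = ppg, video = video,
                 roi_truth = roi_truth, fps = fps, ppg_fs = ppg_fs),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> %d beats, ppg: %s, video: %s\n",
              length(x$truth$beat_times),
              if (is.null(x$ppg)) "none" else sprintf("%g Hz", x$ppg$fs),
              if (is.null(x$video)) "none" else
                sprintf("%d frames @ %g fps", n_frames(x$video), x$video$fps)))
  invisible(x)
}

#' Simulate a full paired study (RR truth + PPG + facial video)
#'
#' One seed drives three deterministic sub-streams (RR jitter, PPG noise,
#' video noise), so a study is fully reproducible from its arguments.
#' Defaults describe the recording conditions the pipeline targets: a
#' 10-minute session filmed at 30 fps with a pulse oximeter sampling at
#' 100 Hz, LF + HF autonomic modulation of the heart rate, a 1% red-channel
#' pulse modulation and mild sensor noise.
#'
#' @param duration_s Study length in seconds.
#' @param mean_hr_bpm Mean heart rate in bpm.
#' @param lf_amp,lf_freq_hz,hf_amp,hf_freq_hz,jitter_sd_ms RR-generator
#'   settings, see [generate_rr_series()].
#' @param ppg_fs PPG sampling rate (Hz).
#' @param ppg_noise_sd PPG noise sd (fraction of pulse amplitude).
#' @param fps,width,height,roi,modulation_depth,video_noise_sd Video
#'   settings, see [synthesize_face_video()].
#' @param seed Integer seed.
#' @return A `synth_study` with `truth`, `ppg` and `video` populated.
#' @export
simulate_study <- function(duration_s = 600, mean_hr_bpm = 70,
                           lf_amp = 0.05, lf_freq_hz = 0.1,
                           hf_amp = 0.05, hf_freq_hz = 0.25,
                           jitter_sd_ms = 0,
                           ppg_fs = 100, ppg_noise_sd = 0.05,
                           fps = 30, width = 64, height = 64,
                           roi = roi_box(width %/% 4, height %/% 4,
                                         width %/% 2, height %/% 2),
                           modulation_depth = 0.01, video_noise_sd = 0.002,
                           seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list((as.integer(seed) * 97L + c(1L, 2L, 3L)) %% .Machine$integer.max)
  truth <- generate_rr_series(duration_s, mean_hr_bpm, lf_amp, lf_freq_hz,
                              hf_amp, hf_freq_hz, jitter_sd_ms, seed = seeds[[1L]])
  ppg <- synthesize_ppg(truth, fs_hz = ppg_fs, noise_sd = ppg_noise_sd,
                        seed = seeds[[2L]])
  study <- synthesize_face_video(truth, fps = fps, width = width, height = height,
                                 roi = roi, modulation_depth = modulation_depth,
                                 noise_sd = video_noise_sd, seed = seeds[[3L]])
  study$ppg <- ppg
  study$ppg_fs <- ppg_fs
  study
}

#' Write a synthetic study to disk
#'
#' Produces `frames/` (PNG sequence), `ppg.csv` (`time_s,amplitude`),
#' `truth.json` (beat times and generator parameters) and `roi.json` in
#' `dir`. PNG output quantizes frames to 8 bits.
#'
#' @param study A `synth_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synth_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(study$video)) write_frames(study$video, file.path(dir, "frames"))
  if (!is.null(study$ppg)) write_ppg_csv(study$ppg, file.path(dir, "ppg.csv"))
  jsonlite::write_json(list(beat_times = study$truth$beat_times,
                            params = study$truth$params),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(study$roi_truth))
    jsonlite::write_json(study$roi_truth[c("x", "y", "w", "h")],
                         file.path(dir, "roi.json"), auto_unbox = TRUE)
  invisible(dir)
}
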