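# End-to-end orchestration: the video and PPG branches, paired-study runs
# and the seeded synthetic experiment batteries used to benchmark the
# pipeline.

default_pipeline_config <- function() {
  list(evm = evm_params(),
       band = c(0.67, 3),
       min_distance_s = 0.33,
       height_k = 0.5,
       min_overlap_s = 60,
       translation_threshold_px = 10,
       fs_interp = 4)
}

#' Run the video branch of the pipeline
#'
#' Crop to the ROI (a fixed box, a supplied track, or automatic skin-region
#' detection with stabilization), magnify colour, and take the spatial red
#' mean — yielding the rPPG pulse signal at the frame rate. The configured
#' pyramid depth is capped at what the cropped frame size supports.
#'
#' @param video A [frame_stack()].
#' @param roi A [roi_box()] (fixed ROI), an [roi_track()], or `"auto"`.
#' @param config Pipeline configuration (see `default_pipeline_config`);
#'   `config$evm` holds the [evm_params()].
#' @return A raw (unfiltered) [pulse_signal()].
#' @export
run_video_branch <- function(video, roi, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  track <- if (inherits(roi, "roi_track")) {
    roi
  } else if (inherits(roi, "roi_box")) {
    fixed_track(video, roi)
  } else if (identical(roi, "auto")) {
    stabilize_track(detect_face_track(video), cfg$translation_threshold_px)
  } else stop("roi must be a roi_box, roi_track or \"auto\"", call. = FALSE)
  cropped <- crop_to_roi(video, track)
  # cap the pyramid depth at what the cropped frame can support
  evm <- cfg$evm
  evm$level <- min(evm$level, floor(log2(min(dim(cropped$frames)[1:2]))))
  magnified <- magnify_color(cropped, evm)
  rm(cropped)
  channel_mean_signal(magnified, "R")
}

#' Detect beats in a pulse signal and derive heart rate and NN intervals
#'
#' The shared back half of both branches: preprocess (detrend + heart-band
#' filter), detect peaks, convert to NN intervals, and compute the
#' count-based heart rate plus the per-minute stratification.
#'
#' @param sig A raw [pulse_signal()] (rPPG red mean or PPG trace).
#' @param config Pipeline configuration.
#' @return List with `train`, `nni`, `hr_count` (bpm), `hr_per_minute`,
#'   `n_peaks`.
#' @export
run_pulse_branch <- function(sig, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  filt <- preprocess_signal(sig, cfg$band)
  train <- detect_peaks(filt, cfg$min_distance_s, cfg$height_k)
  dur <- signal_duration_s(sig)
  list(train = train,
       nni = if (length(train$indices) >= 2L) peaks_to_nni(train) else NULL,
       hr_count = mean_heart_rate(train, dur),
       hr_per_minute = if (dur >= 60) per_minute_heart_rate(train, dur) else numeric(0),
       n_peaks = length(train$indices))
}

#' Run a full paired comparison study
#'
#' For every paired sample: run the video branch (crop, magnify, red mean)
#' and the PPG branch, align the two pulse signals in time, detect beats,
#' and extract the full HRV feature catalogue from each. Across samples:
#' count-based heart-rate error metrics (global and per minute) and the
#' per-feature three-test correlation analysis with Benjamini-Hochberg
#' adjustment.
#'
#' @param studies A list whose elements are either `synth_study` objects or
#'   zero-argument functions returning one (lazy generators keep only one
#'   video in memory at a time).
#' @param config Pipeline configuration overrides; `config$threshold_q` sets
#'   the significance threshold (default 0.5), `config$hrv` is passed to
#'   [extract_all_features()].
#' @param extract_features Set `FALSE` to skip HRV extraction (heart-rate
#'   agreement only).
#' @return A `comparison_report`: `hr` (per-sample table), `metrics`
#'   (global [error_metrics()]), `per_minute` (pooled per-minute metrics and
#'   table), `correlations` (with q-values and significance flags, when >= 4
#'   samples), `n_significant` (per method family), `features_a/b` matrices.
#' @export
run_study <- function(studies, config = list(), extract_features = TRUE) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  nst <- length(studies)
  if (nst < 1L) stop("need at least one study", call. = FALSE)
  cat_names <- hrv_catalog()$name
  hr <- data.frame(sample = seq_len(nst), hr_video = NA_real_, hr_ppg = NA_real_,
                   peaks_video = NA_integer_, peaks_ppg = NA_integer_)
  pm_video <- list(); pm_ppg <- list()
  feat_v <- matrix(NA_real_, nst, length(cat_names), dimnames = list(NULL, cat_names))
  feat_p <- feat_v

  for (i in seq_len(nst)) {
    st <- studies[[i]]
    if (is.function(st)) st <- st()
    stopifnot(inherits(st, "synth_study"))
    rppg <- run_video_branch(st$video, st$roi_truth, cfg)
    st$video <- NULL
    aligned <- align_pair(rppg, st$ppg, cfg$min_overlap_s)
    bv <- run_pulse_branch(aligned$a, cfg)
    bp <- run_pulse_branch(aligned$b, cfg)
    hr$hr_video[i] <- bv$hr_count; hr$hr_ppg[i] <- bp$hr_count
    hr$peaks_video[i] <- bv$n_peaks; hr$peaks_ppg[i] <- bp$n_peaks
    pm_video[[i]] <- bv$hr_per_minute; pm_ppg[[i]] <- bp$hr_per_minute
    if (extract_features && !is.null(bv$nni) && !is.null(bp$nni)) {
      fv <- suppressWarnings(extract_all_features(bv$nni, cfg$hrv %||% list()))
      fp <- suppressWarnings(extract_all_features(bp$nni, cfg$hrv %||% list()))
      feat_v[i, ] <- fv$value; feat_p[i, ] <- fp$value
    }
    rm(st, rppg, aligned); gc(FALSE)
  }

  nmin <- min(lengths(pm_video), lengths(pm_ppg))
  per_minute <- if (nmin >= 1L) {
    pmv <- do.call(rbind, lapply(pm_video, `[`, seq_len(nmin)))
    pmp <- do.call(rbind, lapply(pm_ppg, `[`, seq_len(nmin)))
    data.frame(minute = seq_len(nmin),
               me = colMeans(pmv - pmp),
               mae = colMeans(abs(pmv - pmp)),
               sd = apply(pmv - pmp, 2L, stats::sd))
  }

  correlations <- NULL
  n_significant <- NULL
  if (extract_features) {
    if (nst >= 4L) {
      correlations <- significant_features(
        correlate_feature_tables(feat_v, feat_p),
        threshold_q = cfg$threshold_q %||% 0.5,
        m = length(cat_names))
      tag <- hrv_catalog()$method_tag
      fam <- ifelse(grepl("^freq_", tag), "freq", tag)
      n_significant <- tapply(correlations$significant_all, fam, sum)
    } else {
      warning("fewer than 4 samples: correlation analysis skipped")
    }
  }

  structure(list(hr = hr,
                 metrics = error_metrics(hr$hr_video, hr$hr_ppg),
                 per_minute = per_minute,
                 correlations = correlations,
                 n_significant = n_significant,
                 features_video = feat_v, features_ppg = feat_p,
                 config = cfg),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d samples\n", nrow(x$hr)))
  print(x$metrics)
  if (!is.null(x$correlations))
    cat(sprintf("  significant under all three tests: %d / %d features\n",
                sum(x$correlations$significant_all, na.rm = TRUE),
                nrow(x$correlations)))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' `report.tsv` holds the per-feature correlation table; `report.json` holds
#' the heart-rate table, error metrics and per-minute stratification.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$correlations))
    utils::write.table(report$correlations, file.path(dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(hr = report$hr, metrics = unclass(report$metrics),
         per_minute = report$per_minute,
         n_significant = as.list(report$n_significant)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Battery of lazily generated paired synthetic studies
#'
#' One generator per seed; mean heart rates are spread evenly over
#' `hr_range` so the correlation analysis sees between-sample variation.
#' Each element, when called, returns a fresh `synth_study`, so only one
#' video needs to exist in memory at a time.
#'
#' @param seeds Integer seeds, one study per seed.
#' @param hr_range Mean-heart-rate range in bpm covered across studies.
#' @param ... Further arguments forwarded to [simulate_study()].
#' @return List of zero-argument generator functions.
#' @export
synthetic_study_battery <- function(seeds, hr_range = c(55, 90), ...) {
  n <- length(seeds)
  hrs <- if (n == 1L) mean(hr_range) else seq(hr_range[1L], hr_range[2L], length.out = n)
  dots <- list(...)
  lapply(seq_len(n), function(i) {
    force(i)
    function() do.call(simulate_study,
                       c(list(mean_hr_bpm = hrs[i], seed = seeds[i]), dots))
  })
}

#' Benchmark the peak detector on synthetic PPG traces
#'
#' Generates one seeded PPG trace per seed (heart rates spread over
#' `hr_range`, LF + HF autonomic modulation, Gaussian pulses, additive
#' noise), runs preprocessing and peak detection, and matches detections to
#' the ground-truth beat times within `tolerance_s`. Precision and recall
#' are pooled over all traces.
#'
#' @param seeds Integer seeds, one trace per seed.
#' @param duration_s Trace length in seconds.
#' @param fs_hz PPG sampling rate.
#' @param noise_sd Noise sd as a fraction of the pulse amplitude.
#' @param hr_range Mean-heart-rate range across traces (bpm).
#' @param lf_amp,hf_amp Modulation amplitudes of the RR generator.
#' @param tolerance_s Match tolerance in seconds.
#' @param config Pipeline configuration overrides.
#' @return List with pooled `precision`, `recall` (fractions), counts, and
#'   the per-trace table.
#' @export
peak_detection_benchmark <- function(seeds, duration_s = 600, fs_hz = 100,
                                     noise_sd = 0.05, hr_range = c(55, 90),
                                     lf_amp = 0.05, hf_amp = 0.05,
                                     tolerance_s = 0.05, config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  n <- length(seeds)
  hrs <- if (n == 1L) mean(hr_range) else seq(hr_range[1L], hr_range[2L], length.out = n)
  per <- data.frame(seed = seeds, matched = NA_integer_,
                    detected = NA_integer_, truth = NA_integer_)
  for (i in seq_len(n)) {
    truth <- generate_rr_series(duration_s, hrs[i], lf_amp = lf_amp,
                                hf_amp = hf_amp, seed = seeds[i])
    ppg <- synthesize_ppg(truth, fs_hz = fs_hz, noise_sd = noise_sd,
                          seed = seeds[i] + 10000L)
    train <- detect_peaks(preprocess_signal(ppg, cfg$band),
                          cfg$min_distance_s, cfg$height_k)
    m <- match_peaks(train$times, truth$beat_times, tolerance_s)
    per$matched[i] <- m$n_matched
    per$detected[i] <- m$n_detected
    per$truth[i] <- m$n_truth
  }
  list(precision = sum(per$matched) / sum(per$detected),
       recall = sum(per$matched) / sum(per$truth),
       n_matched = sum(per$matched), n_detected = sum(per$detected),
       n_truth = sum(per$truth), per_trace = per)
}
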