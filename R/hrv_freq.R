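# Frequency-domain HRV: tachogram resampling, three PSD estimators and the
# per-band feature block.
#
# Estimator settings follow community practice for short-term HRV: the
# tachogram is cubic-resampled at 4 Hz; Welch uses 256-sample (64 s)
# Hann-windowed segments with 50% overlap zero-padded to 4096 bins; the
# autoregressive estimator is a Burg all-pole model of order 16; and the
# Lomb-Scargle estimator works on the uneven (time, interval) pairs directly
# with 4x frequency oversampling.

#' Standard HRV frequency bands
#'
#' Very-low `[0, 0.04)` Hz, low `[0.04, 0.15)` Hz, high `[0.15, 0.4]` Hz.
#'
#' @param vlf,lf,hf Band edges `c(lo, hi)` in Hz; must be contiguous and
#'   increasing.
#' @return An object of class `freq_bands`.
#' @export
freq_bands <- function(vlf = c(0, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4)) {
  e <- c(vlf, lf, hf)
  if (is.unsorted(c(vlf[1L], vlf[2L], lf[2L], hf[2L]), strictly = TRUE) ||
      vlf[2L] != lf[1L] || lf[2L] != hf[1L])
    stop("bands must be contiguous, non-overlapping and increasing", call. = FALSE)
  structure(list(vlf = vlf, lf = lf, hf = hf), class = "freq_bands")
}

#' Resample an NN-interval series onto a uniform grid
#'
#' Cubic (natural spline) interpolation of the tachogram `nni(t)` onto a
#' uniform grid at `fs_interp`, spanning the recording; Welch and AR spectra
#' need an evenly sampled series. Falls back to linear interpolation with a
#' warning when fewer than 4 intervals are available.
#'
#' @param nni An [nni_series()].
#' @param fs_interp Resampling rate in Hz (default 4).
#' @return A [pulse_signal()] in ms units.
#' @export
resample_nni <- function(nni, fs_interp = 4) {
  stopifnot(inherits(nni, "nni_series"))
  t <- nni$t; y <- nni$nni
  if (length(y) < 2L) stop("need at least 2 intervals to resample", call. = FALSE)
  grid <- seq(t[1L], t[length(t)], by = 1 / fs_interp)
  v <- if (length(y) < 4L) {
    warning("fewer than 4 intervals: falling back to linear interpolation")
    stats::approx(t, y, xout = grid)$y
  } else {
    stats::spline(t, y, xout = grid, method = "natural")$y
  }
  pulse_signal(v, fs = fs_interp, t0 = t[1L])
}

psd_object <- function(freqs, power, method) {
  power <- pmax(power, 0)
  structure(list(freqs = freqs, power = power, method = method),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %s, %d bins over [%.4g, %.4g] Hz\n",
              x$method, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# Welch averaged modified periodogram of a uniform series (one-sided,
# units^2/Hz).
welch_psd <- function(values, fs, seg_len = 256L, overlap = 0.5, nfft = 4096L) {
  x <- values - mean(values)
  n <- length(x)
  if (n < seg_len) stop("series shorter than one Welch segment", call. = FALSE)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1L)) / (seg_len - 1L))  # Hann
  nfft <- max(nfft, seg_len)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - seg_len)))
    acc <- acc + Mod(X[1:(nfft %/% 2L + 1L)])^2
  }
  psd <- acc / (length(starts) * fs * sum(w^2))
  psd[2:(nfft %/% 2L)] <- 2 * psd[2:(nfft %/% 2L)]  # one-sided (not DC/Nyquist)
  list(freqs = (0:(nfft %/% 2L)) * fs / nfft, power = psd)
}

# Burg autoregressive PSD of a uniform series (one-sided, units^2/Hz).
burg_psd <- function(values, fs, order = 16L, n_freq = 8192L) {
  x <- values - mean(values)
  if (length(x) <= order + 1L) stop("series too short for the AR order", call. = FALSE)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  freqs <- seq(0, fs / 2, length.out = n_freq + 1L)
  om <- outer(freqs / fs * 2 * pi, seq_along(a))
  denom <- Mod(1 - (cos(om) %*% a) - 1i * (-(sin(om) %*% a)))^2
  psd <- drop(fit$var.pred / fs / denom)
  psd[-c(1L, length(psd))] <- 2 * psd[-c(1L, length(psd))]
  list(freqs = freqs, power = psd)
}

# Lomb-Scargle least-squares periodogram of the uneven (t, y) series.
# The classical tau-shifted estimator; the raw powers are rescaled so that
# the trapezoid integral over the evaluated grid equals the sample variance,
# giving a PSD in units^2/Hz comparable with the uniform-grid estimators.
lomb_psd <- function(t, y, f_max = 0.5, ofac = 4) {
  y <- y - mean(y)
  n <- length(y)
  if (n < 4L) stop("need at least 4 points for a Lomb-Scargle spectrum", call. = FALSE)
  span <- t[n] - t[1L]
  df <- 1 / (ofac * span)
  freqs <- seq(df, f_max, by = df)
  P <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1L))
  total <- trapz(freqs, P)
  scale <- if (is.finite(total) && total > 0) stats::var(y) / total else 0
  list(freqs = freqs, power = P * scale)
}

#' Power spectral density of an NN-interval series
#'
#' Three estimator families over the same series: `welch` and `ar` consume
#' the uniformly resampled tachogram (see [resample_nni()]), `lomb` consumes
#' the uneven `(time, interval)` pairs directly. All return a one-sided PSD
#' in ms^2/Hz.
#'
#' @param nni An [nni_series()].
#' @param method `"welch"`, `"ar"` or `"lomb"`.
#' @param settings Optional overrides: `fs_interp`, `seg_len`, `overlap`,
#'   `nfft` (welch); `fs_interp`, `order`, `n_freq` (ar); `f_max`, `ofac`
#'   (lomb).
#' @return A `psd_estimate` with `freqs`, `power`, `method`.
#' @export
psd_estimate <- function(nni, method = c("welch", "ar", "lomb"), settings = list()) {
  stopifnot(inherits(nni, "nni_series"))
  method <- match.arg(method)
  s <- utils::modifyList(list(fs_interp = 4, seg_len = 256L, overlap = 0.5,
                              nfft = 4096L, order = 16L, n_freq = 8192L,
                              f_max = 0.5, ofac = 4), settings)
  res <- switch(method,
    welch = {
      rs <- resample_nni(nni, s$fs_interp)
      welch_psd(rs$values, rs$fs, s$seg_len, s$overlap, s$nfft)
    },
    ar = {
      rs <- resample_nni(nni, s$fs_interp)
      burg_psd(rs$values, rs$fs, s$order, s$n_freq)
    },
    lomb = lomb_psd(nni$t, nni$nni, s$f_max, s$ofac))
  psd_object(res$freqs, res$power, method)
}

#' Band-power features from a PSD estimate
#'
#' For each band (VLF, LF, HF): the peak frequency (argmax of power within
#' the band), the absolute power (trapezoidal integral, ms^2), the relative
#' power (absolute power over the sum across the three bands, so the three
#' relative powers sum to 1) and the natural-log absolute power. A band not
#' covered by the frequency grid yields `NA` (flagged missing, not silently
#' zero).
#'
#' @param psd A [psd_estimate()].
#' @param bands A [freq_bands()].
#' @return Named numeric vector of 12 features
#'   (`<method>_<band>_<peak|abs|rel|log>`).
#' @export
band_features <- function(psd, bands = freq_bands()) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$freqs; p <- psd$power
  one_band <- function(lim, closed_hi) {
    m <- f >= lim[1L] & (if (closed_hi) f <= lim[2L] else f < lim[2L])
    if (sum(m) < 2L) return(c(peak = NA_real_, abs = NA_real_))
    c(peak = f[m][which.max(p[m])], abs = trapz(f[m], p[m]))
  }
  res <- list(vlf = one_band(bands$vlf, FALSE),
              lf = one_band(bands$lf, FALSE),
              hf = one_band(bands$hf, TRUE))
  abs_p <- vapply(res, `[[`, numeric(1L), "abs")
  total <- sum(abs_p)
  out <- unlist(lapply(names(res), function(b) {
    a <- res[[b]][["abs"]]
    stats::setNames(c(res[[b]][["peak"]], a, a / total, log(a)),
                    paste0(psd$method, "_", b, c("_peak", "_abs", "_rel", "_log")))
  }))
  out
}

freq_feature_names <- function(method) {
  as.vector(vapply(c("vlf", "lf", "hf"),
                   function(b) paste0(method, "_", b, c("_peak", "_abs", "_rel", "_log")),
                   character(4L)))
}

FREQ_UNITS_PER_BAND <- c("Hz", "ms^2", "", "ln(ms^2)")
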