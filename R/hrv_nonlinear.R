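# Non-linear HRV features: Poincare geometry, sample entropy and detrended
# fluctuation analysis.

#' Poincare-plot features
#'
#' From the lag-1 scatter `(nni[i], nni[i+1])`:
#' \deqn{SD1 = \sqrt{\mathrm{var}(\Delta)/2}, \quad
#'       SD2 = \sqrt{2\,\mathrm{var}(x) - \mathrm{var}(\Delta)/2}}
#' with \eqn{\Delta} the successive differences — the dispersion
#' perpendicular to and along the line of identity. Also returns the
#' SD1/SD2 ratio (missing when `SD2 == 0`) and the fitted ellipse area
#' `pi * SD1 * SD2`.
#'
#' @param nni An [nni_series()] or numeric vector of intervals (>= 3).
#' @return Named vector `sd1, sd2, sd_ratio, ellipse_area` (ms, ms, -, ms^2).
#' @export
poincare_features <- function(nni) {
  x <- if (inherits(nni, "nni_series")) nni$nni else as.numeric(nni)
  if (length(x) < 3L) stop("need at least 3 intervals for a Poincare plot", call. = FALSE)
  d <- diff(x)
  sd1 <- sqrt(stats::var(d) / 2)
  sd2sq <- 2 * stats::var(x) - stats::var(d) / 2
  sd2 <- sqrt(max(sd2sq, 0))
  c(sd1 = sd1, sd2 = sd2,
    sd_ratio = if (sd2 > 0) sd1 / sd2 else NA_real_,
    ellipse_area = pi * sd1 * sd2)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` and `A` count pairs of templates of
#' length `m` and `m + 1` whose Chebyshev distance is below `r * sd(x)`,
#' self-matches excluded. Low values indicate regularity (a perfectly
#' periodic series scores near 0); whitening a series cannot decrease it.
#'
#' @param nni An [nni_series()] or numeric vector (length >= 10 * m).
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the series SD (default 0.2).
#' @return The entropy value, or `NA` (with a warning) when no template pair
#'   matches at either length.
#' @export
sample_entropy <- function(nni, m = 2L, r = 0.2) {
  x <- if (inherits(nni, "nni_series")) nni$nni else as.numeric(nni)
  n <- length(x)
  if (n < 10L * m) stop("series too short for sample entropy", call. = FALSE)
  tol <- r * stats::sd(x)
  # Chebyshev template-pair counts, built incrementally: D holds the max
  # coordinate distance over the current template length for all i < j.
  count_pairs <- function(len) {
    nt <- n - len + 1L
    D <- abs(outer(x[1:nt], x[1:nt], "-"))
    if (len > 1L) for (k in 1:(len - 1L)) {
      D <- pmax(D, abs(outer(x[(1L + k):(nt + k)], x[(1L + k):(nt + k)], "-")))
    }
    (sum(D < tol) - nt) / 2  # strict tolerance, self-matches excluded
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (A == 0 || B == 0) {
    warning("sample entropy undefined: no template matches at one length")
    return(NA_real_)
  }
  -log(A / B)
}

#' Detrended fluctuation analysis
#'
#' The mean-centred series is integrated; for each window size `n` the
#' profile is split into non-overlapping windows, each window is detrended
#' by a least-squares line, and the RMS residual fluctuation `F(n)` is
#' computed. The scaling exponents are the slopes of `log F` versus `log n`:
#' `alpha1` over the short scales (4-16 beats), `alpha2` over the long scales
#' (16-64 beats), `alpha_overall` over both. White noise scales with
#' `alpha ~ 0.5`, integrated white noise with `alpha ~ 1.5`.
#'
#' @param nni An [nni_series()] or numeric vector.
#' @param short_scales,long_scales Window sizes (beats) for the two regimes.
#' @return List with `alpha1`, `alpha2`, `alpha_overall`, and the `scales` /
#'   `fluctuation` table. `alpha2` is `NA` when the series is shorter than
#'   four times the largest long scale.
#' @export
dfa <- function(nni, short_scales = 4:16, long_scales = 16:64) {
  x <- if (inherits(nni, "nni_series")) nni$nni else as.numeric(nni)
  n <- length(x)
  if (n < 4L * max(short_scales))
    stop("series too short for DFA at the requested short scales", call. = FALSE)
  have_long <- n >= 4L * max(long_scales)
  scales <- sort(unique(c(short_scales, if (have_long) long_scales)))
  y <- cumsum(x - mean(x))
  fluct <- vapply(scales, function(s) {
    nw <- n %/% s
    idx <- seq_len(nw * s)
    win <- matrix(y[idx], nrow = s)
    tt <- seq_len(s)
    # closed-form linear detrend per window
    tc <- tt - mean(tt)
    denom <- sum(tc^2)
    slopes <- colSums(win * tc) / denom
    resid <- win - outer(tc, slopes) - matrix(colMeans(win), s, nw, byrow = TRUE)
    sqrt(mean(resid^2))
  }, numeric(1L))
  fit_alpha <- function(sel) {
    if (sum(sel) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(log(fluct[sel]) ~ log(scales[sel])))[2L])
  }
  list(alpha1 = fit_alpha(scales %in% short_scales),
       alpha2 = if (have_long) fit_alpha(scales %in% long_scales) else NA_real_,
       alpha_overall = fit_alpha(rep(TRUE, length(scales))),
       scales = scales, fluctuation = fluct)
}

NONLINEAR_NAMES <- c("sd1", "sd2", "sd_ratio", "ellipse_area", "sampen",
                     "dfa_alpha1", "dfa_alpha2", "dfa_alpha_overall",
                     "csi", "cvi", "sd2_sd1_ratio", "poincare_corr")

NONLINEAR_UNITS <- c(sd1 = "ms", sd2 = "ms", sd_ratio = "", ellipse_area = "ms^2",
                     sampen = "", dfa_alpha1 = "", dfa_alpha2 = "",
                     dfa_alpha_overall = "", csi = "", cvi = "",
                     sd2_sd1_ratio = "", poincare_corr = "")

# The 12-feature non-linear block: Poincare geometry and its derived
# indices (CSI = SD2/SD1, CVI = log10(16 * SD1 * SD2)), sample entropy,
# the three DFA exponents, and the lag-1 autocorrelation of the intervals.
nonlinear_features <- function(nni, sampen_m = 2L, sampen_r = 0.2) {
  x <- if (inherits(nni, "nni_series")) nni$nni else as.numeric(nni)
  pc <- poincare_features(x)
  se <- tryCatch(suppressWarnings(sample_entropy(x, sampen_m, sampen_r)),
                 error = function(e) NA_real_)
  df <- tryCatch(dfa(x), error = function(e)
    list(alpha1 = NA_real_, alpha2 = NA_real_, alpha_overall = NA_real_))
  n <- length(x)
  pcorr <- if (stats::sd(x) > 0) stats::cor(x[-n], x[-1L]) else NA_real_
  prod16 <- 16 * pc[["sd1"]] * pc[["sd2"]]
  c(sd1 = pc[["sd1"]], sd2 = pc[["sd2"]], sd_ratio = pc[["sd_ratio"]],
    ellipse_area = pc[["ellipse_area"]],
    sampen = se,
    dfa_alpha1 = df$alpha1, dfa_alpha2 = df$alpha2,
    dfa_alpha_overall = df$alpha_overall,
    csi = if (pc[["sd1"]] > 0) pc[["sd2"]] / pc[["sd1"]] else NA_real_,
    cvi = if (prod16 > 0) log10(prod16) else NA_real_,
    sd2_sd1_ratio = if (pc[["sd1"]] > 0) pc[["sd2"]] / pc[["sd1"]] else NA_real_,
    poincare_corr = pcorr)
}
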