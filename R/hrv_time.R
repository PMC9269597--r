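# Time-domain HRV features.

TIME_DOMAIN_NAMES <- c("nni_count", "nni_mean", "nni_min", "nni_max",
                       "nni_diff_mean", "hr_mean", "hr_min", "hr_max",
                       "sdnn", "rmssd", "sdsd", "nn20", "pnn20",
                       "nn50", "pnn50")

TIME_DOMAIN_UNITS <- c(nni_count = "count", nni_mean = "ms", nni_min = "ms",
                       nni_max = "ms", nni_diff_mean = "ms", hr_mean = "bpm",
                       hr_min = "bpm", hr_max = "bpm", sdnn = "ms",
                       rmssd = "ms", sdsd = "ms", nn20 = "count",
                       pnn20 = "%", nn50 = "count", pnn50 = "%")

#' Time-domain HRV features
#'
#' Computes the 15-feature time-domain catalogue from an NN-interval series:
#' interval count, mean/min/max NN interval, mean absolute successive
#' difference, instantaneous heart-rate (60000/NN) mean/min/max, SDNN (SD of
#' the intervals), RMSSD (root mean square of successive differences), SDSD
#' (SD of successive differences), and the NN20/pNN20/NN50/pNN50 family.
#' `nnXX` counts successive differences strictly greater than XX ms in
#' magnitude; `pnnXX` is that count as a percentage of all differences.
#'
#' @param nni An [nni_series()] with at least 3 intervals (successive-
#'   difference statistics need two differences).
#' @return Named numeric vector of the 15 features, in catalogue order.
#' @export
time_domain_features <- function(nni) {
  x <- if (inherits(nni, "nni_series")) nni$nni else as.numeric(nni)
  if (length(x) < 2L)
    stop("too few intervals for time-domain features (sdnn needs >= 2)", call. = FALSE)
  if (length(x) < 3L)
    stop("too few intervals for successive-difference features (sdsd needs >= 3)", call. = FALSE)
  d <- diff(x)
  hr <- 60000 / x
  nn20 <- sum(abs(d) > 20)
  nn50 <- sum(abs(d) > 50)
  out <- c(nni_count = length(x),
           nni_mean = mean(x), nni_min = min(x), nni_max = max(x),
           nni_diff_mean = mean(abs(d)),
           hr_mean = mean(hr), hr_min = min(hr), hr_max = max(hr),
           sdnn = stats::sd(x),
           rmssd = sqrt(mean(d^2)),
           sdsd = stats::sd(d),
           nn20 = nn20, pnn20 = 100 * nn20 / length(d),
           nn50 = nn50, pnn50 = 100 * nn50 / length(d))
  out[TIME_DOMAIN_NAMES]
}
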