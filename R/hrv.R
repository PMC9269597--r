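# Full HRV feature catalogue: 15 time-domain + 36 frequency-domain
# (12 per spectral estimator) + 12 non-linear = 63 named features.

PSD_METHODS <- c("welch", "ar", "lomb")

#' The fixed HRV feature catalogue
#'
#' @return A data.frame with columns `name`, `method_tag`
#'   (`time | freq_welch | freq_ar | freq_lomb | nonlinear`) and `units`,
#'   63 rows in deterministic order.
#' @export
hrv_catalog <- function() {
  freq <- do.call(rbind, lapply(PSD_METHODS, function(m)
    data.frame(name = freq_feature_names(m),
               method_tag = paste0("freq_", m),
               units = rep(FREQ_UNITS_PER_BAND, 3L))))
  rbind(
    data.frame(name = TIME_DOMAIN_NAMES, method_tag = "time",
               units = unname(TIME_DOMAIN_UNITS[TIME_DOMAIN_NAMES])),
    freq,
    data.frame(name = NONLINEAR_NAMES, method_tag = "nonlinear",
               units = unname(NONLINEAR_UNITS[NONLINEAR_NAMES]))
  )
}

#' Extract the full HRV feature set from an NN-interval series
#'
#' Runs all three method families — time-domain statistics, band powers under
#' the Welch, autoregressive and Lomb-Scargle spectral estimators, and the
#' non-linear block — and returns one named value per catalogue entry in a
#' deterministic order. A family that fails (e.g. a series too short for a
#' Welch segment) contributes `NA` values flagged in the `missing` column
#' rather than aborting the extraction; `strict = TRUE` turns any missing
#' family into an error.
#'
#' @param nni An [nni_series()].
#' @param config Optional list: `bands` (a [freq_bands()]), `psd_settings`
#'   (passed to [psd_estimate()]), `sampen_m`, `sampen_r`.
#' @param strict Error on any failed family instead of flagging missing.
#' @return An `hrv_feature_set`: data.frame with `name`, `value`, `units`,
#'   `method_tag`, `missing`.
#' @export
extract_all_features <- function(nni, config = list(), strict = FALSE) {
  stopifnot(inherits(nni, "nni_series"))
  bands <- config$bands %||% freq_bands()
  psd_settings <- config$psd_settings %||% list()
  cat_df <- hrv_catalog()
  vals <- stats::setNames(rep(NA_real_, nrow(cat_df)), cat_df$name)

  fill <- function(v) vals[names(v)] <<- v
  failed <- character(0)
  try_family <- function(label, expr) {
    tryCatch(fill(expr), error = function(e) {
      failed <<- c(failed, sprintf("%s (%s)", label, conditionMessage(e)))
      NULL
    })
  }

  try_family("time", time_domain_features(nni))
  for (m in PSD_METHODS) {
    try_family(paste0("freq_", m),
               band_features(psd_estimate(nni, m, psd_settings), bands))
  }
  try_family("nonlinear",
             nonlinear_features(nni, config$sampen_m %||% 2L,
                                config$sampen_r %||% 0.2))

  if (strict && length(failed))
    stop("feature families failed: ", paste(failed, collapse = "; "), call. = FALSE)
  if (length(failed))
    warning("feature families incomplete: ", paste(failed, collapse = "; "))

  out <- data.frame(name = cat_df$name, value = unname(vals[cat_df$name]),
                    units = cat_df$units, method_tag = cat_df$method_tag,
                    missing = !is.finite(unname(vals[cat_df$name])))
  class(out) <- c("hrv_feature_set", "data.frame")
  out
}

#' @export
print.hrv_feature_set <- function(x, ...) {
  cat(sprintf("<hrv_feature_set> %d features (%d missing): %s\n",
              nrow(x), sum(x$missing),
              paste(sprintf("%s=%d", unique(x$method_tag),
                            as.vector(table(x$method_tag)[unique(x$method_tag)])),
                    collapse = ", ")))
  NextMethod()
}

#' Write an HRV feature set as JSON or TSV
#'
#' @param features An `hrv_feature_set`.
#' @param path Output file; format chosen by extension (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(features, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(features, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
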