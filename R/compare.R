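# Dual-source agreement analysis: time alignment, heart-rate error metrics,
# per-feature correlation under three tests, and Benjamini-Hochberg FDR
# control.

#' Symmetric time alignment of a signal/peak-train pair
#'
#' The pulse-oximeter run and the video recording rarely start and stop at
#' exactly the same instant, so the longer member is trimmed by the same
#' amount at the beginning and at the end until both durations match (within
#' one sample for sampled signals); an odd surplus sample is removed from the
#' end. Works on any combination of [pulse_signal()] and [peak_train()].
#'
#' @param a,b The two members.
#' @param min_overlap_s Error if the common duration after trimming is
#'   shorter than this (default 60 s, one full per-minute window).
#' @return `list(a =, b =)` with the longer member trimmed.
#' @export
align_pair <- function(a, b, min_overlap_s = 60) {
  dur <- function(x) if (inherits(x, "pulse_signal")) signal_duration_s(x) else x$duration_s
  da <- dur(a); db <- dur(b)
  target <- min(da, db)
  if (target < min_overlap_s)
    stop(sprintf("common duration %.1f s is shorter than %.0f s", target, min_overlap_s),
         call. = FALSE)
  trim <- function(x, d) {
    if (d <= target) return(x)
    if (inherits(x, "pulse_signal")) {
      n <- length(x$values)
      k <- n - round(target * x$fs)
      if (k <= 0L) return(x)
      i0 <- floor(k / 2)
      pulse_signal(x$values[(i0 + 1L):(n - (k - i0))], x$fs, x$t0 + i0 / x$fs)
    } else {
      cut <- (d - target) / 2
      lo <- x$t0 + cut; hi <- x$t0 + d - cut
      keep <- x$times >= lo & x$times < hi
      structure(list(indices = x$indices[keep], times = x$times[keep],
                     fs = x$fs, t0 = lo, duration_s = target),
                class = "peak_train")
    }
  }
  list(a = trim(a, da), b = trim(b, db))
}

#' Heart-rate error metrics between two sources
#'
#' Elementwise differences `d = a - b`, then: Me (signed mean error — the
#' sign is retained), MAE (mean absolute error), SD of the differences
#' (sample SD) and RMSE. The SDs of the two heart-rate vectors themselves
#' are also reported, because "SD" in agreement tables is sometimes the
#' dispersion of the rates rather than of their differences.
#'
#' @param hr_a,hr_b Equal-length numeric bpm vectors.
#' @return An `error_metrics` object: `me`, `mae`, `sd`, `rmse`, `sd_a`,
#'   `sd_b`, `n`.
#' @export
error_metrics <- function(hr_a, hr_b) {
  if (length(hr_a) != length(hr_b)) stop("length mismatch", call. = FALSE)
  if (length(hr_a) < 1L) stop("need at least one pair", call. = FALSE)
  d <- hr_a - hr_b
  structure(list(me = mean(d), mae = mean(abs(d)),
                 sd = if (length(d) > 1L) stats::sd(d) else 0,
                 rmse = sqrt(mean(d^2)),
                 sd_a = if (length(d) > 1L) stats::sd(hr_a) else 0,
                 sd_b = if (length(d) > 1L) stats::sd(hr_b) else 0,
                 n = length(d)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("<error_metrics> n=%d  Me=%.4f  MAE=%.4f  SD(diff)=%.4f  RMSE=%.4f\n",
              x$n, x$me, x$mae, x$sd, x$rmse))
  invisible(x)
}

#' Per-feature correlation between two feature tables
#'
#' For every shared feature column: Pearson product-moment r, Spearman rank
#' r and Kendall tau-b (tie-corrected), each with its two-sided p-value.
#' Pairs with missing values are dropped per feature; a feature with fewer
#' than 4 complete pairs or zero variance in either column gets `NA`
#' coefficients.
#'
#' @param tab_a,tab_b Samples x features matrices or data.frames with
#'   identical dimensions and column names.
#' @return A data.frame with one row per feature: `feature`, `n`,
#'   `r_pearson`, `p_pearson`, `r_spearman`, `p_spearman`, `tau_kendall`,
#'   `p_kendall`.
#' @export
correlate_feature_tables <- function(tab_a, tab_b) {
  tab_a <- as.matrix(tab_a); tab_b <- as.matrix(tab_b)
  if (!identical(dim(tab_a), dim(tab_b)))
    stop("feature tables must have identical shape", call. = FALSE)
  if (!identical(colnames(tab_a), colnames(tab_b)))
    stop("feature tables must share column names", call. = FALSE)
  one <- function(j) {
    x <- tab_a[, j]; y <- tab_b[, j]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    na <- c(r = NA_real_, p = NA_real_)
    res <- c(n = sum(ok))
    if (sum(ok) < 4L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(res, pearson = na, spearman = na, kendall = na))
    ct <- function(method) {
      h <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
      c(r = unname(h$estimate), p = h$p.value)
    }
    c(res, pearson = ct("pearson"), spearman = ct("spearman"), kendall = ct("kendall"))
  }
  m <- t(vapply(colnames(tab_a), one, numeric(7L)))
  data.frame(feature = colnames(tab_a), n = m[, "n"],
             r_pearson = m[, "pearson.r"], p_pearson = m[, "pearson.p"],
             r_spearman = m[, "spearman.r"], p_spearman = m[, "spearman.p"],
             tau_kendall = m[, "kendall.r"], p_kendall = m[, "kendall.p"],
             row.names = NULL)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q(i) = min over p(j) >= p(i) of m * p(j) / rank(j)`, capped at 1 and
#' returned in input order. The family size `m` defaults to the vector
#' length but can be set to the full feature-catalogue size when some tests
#' are missing.
#'
#' @param pvalues Numeric p-values in `[0, 1]` (`NA` passes through).
#' @param m Family size for the adjustment.
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(pvalues, m = length(pvalues)) {
  p <- as.numeric(pvalues)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH", n = max(m, sum(!is.na(p))))
}

#' Attach q-values and significance flags to a correlation table
#'
#' Adjusts each test's p-value column over its own family (one BH family per
#' test, sized by the feature catalogue), then flags a feature as
#' `significant_all` when its q-value is below `threshold_q` under all three
#' tests.
#'
#' @param corr A [correlate_feature_tables()] result.
#' @param threshold_q Significance threshold on the q-value (default 0.5).
#' @param m Family size per test (default: number of rows).
#' @return `corr` with `q_pearson`, `q_spearman`, `q_kendall`,
#'   `sig_pearson`, `sig_spearman`, `sig_kendall`, `significant_all`.
#' @export
significant_features <- function(corr, threshold_q = 0.5, m = nrow(corr)) {
  for (test in c("pearson", "spearman", "kendall")) {
    q <- benjamini_hochberg(corr[[paste0("p_", test)]], m = m)
    corr[[paste0("q_", test)]] <- q
    corr[[paste0("sig_", test)]] <- !is.na(q) & q < threshold_q
  }
  corr$significant_all <- corr$sig_pearson & corr$sig_spearman & corr$sig_kendall
  corr
}
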