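# Reference-comparison statistics: 95% confidence intervals and overlap,
# normalization to a reference, percent differences, Bland-Altman agreement.

#' 95% confidence interval from a mean and SD
#'
#' `mean +/- 1.96 * sd` by default — the interval plotted for replicate
#' measurements without a standard-error or t correction. Setting
#' `se_based = TRUE` with `n` uses `mean +/- t_{0.975, n-1} * sd / sqrt(n)`
#' for sensitivity analyses.
#'
#' @param mean,sd summary statistics (`sd >= 0`).
#' @param se_based use a t-based standard-error interval instead.
#' @param n replicate count, required when `se_based`.
#' @return Numeric `c(lo, hi)`.
#' @export
ci95 <- function(mean, sd, se_based = FALSE, n = NULL) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (se_based) {
    if (is.null(n) || n < 2) stop("`n` >= 2 required for se_based interval", call. = FALSE)
    half <- stats::qt(0.975, n - 1) * sd / sqrt(n)
  } else half <- 1.96 * sd
  c(mean - half, mean + half)
}

#' Do two closed intervals overlap?
#'
#' Touching endpoints count as overlap (closed-interval convention).
#'
#' @param a,b numeric `c(lo, hi)`.
#' @export
intervals_overlap <- function(a, b) {
  if (a[1] > a[2] || b[1] > b[2]) stop("interval lo > hi", call. = FALSE)
  a[1] <= b[2] && b[1] <= a[2]
}

#' Normalize test values to a reference value
#'
#' @param test_values numeric vector.
#' @param ref_value nonzero scalar reference.
#' @return `test_values / ref_value`.
#' @export
normalize_to_reference <- function(test_values, ref_value) {
  if (length(ref_value) != 1L || !is.finite(ref_value) || ref_value == 0)
    stop("`ref_value` must be a single nonzero value", call. = FALSE)
  test_values / ref_value
}

#' Mean percent difference between paired test and reference values
#'
#' `mean(|test - ref| / ref) * 100` over the pairs. The signed version
#' (`mean((test - ref)/ref) * 100`) is returned in attribute `"signed"`.
#'
#' @param test_means,ref_means equal-length numeric vectors; `ref_means`
#'   must be nonzero.
#' @export
mean_percent_difference <- function(test_means, ref_means) {
  if (length(test_means) != length(ref_means))
    stop("length mismatch", call. = FALSE)
  if (any(ref_means == 0)) stop("reference values must be nonzero", call. = FALSE)
  out <- mean(abs(test_means - ref_means) / ref_means) * 100
  attr(out, "signed") <- mean((test_means - ref_means) / ref_means) * 100
  out
}

#' Bland-Altman agreement between two paired measurement methods
#'
#' Both lists are first normalized by the grand mean of all `2n` values,
#' then per-pair differences `a - b` and averages are formed. Returns the
#' mean difference and the +/-1.96 SD limits of agreement. The convention
#' here mirrors "automatic minus manual": pass the automatic measurements
#' as `values_a`.
#'
#' @param values_a,values_b per-subject measurements, equal length >= 2.
#' @return Object of class `bland_altman`: `mean_difference`, `loa_low`,
#'   `loa_high`, `pairs_n`, plus the per-pair `averages` and `differences`
#'   in normalized units.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("length mismatch between paired lists", call. = FALSE)
  n <- length(values_a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  gm <- mean(c(values_a, values_b))
  if (gm == 0) stop("grand mean is zero; cannot normalize", call. = FALSE)
  a <- values_a / gm
  b <- values_b / gm
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_difference = md,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 pairs_n = n, averages = (a + b) / 2, differences = d,
                 grand_mean = gm),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d  mean diff %.4g  LoA [%.4g, %.4g] (normalized units)\n",
              x$pairs_n, x$mean_difference, x$loa_low, x$loa_high))
  invisible(x)
}

#' Build a comparison record between a test and a reference measurement
#'
#' @param sample_id identifier.
#' @param test_mean,test_sd test-method summary (e.g. imaging protocol).
#' @param ref_mean,ref_sd reference summary (e.g. bench NMR).
#' @param se_based,n_test,n_ref forwarded to [ci95()].
#' @return One-row data.frame with both CIs, the closed-interval overlap
#'   flag, the normalized test value, and the percent difference.
#' @export
comparison_record <- function(sample_id, test_mean, test_sd, ref_mean, ref_sd,
                              se_based = FALSE, n_test = NULL, n_ref = NULL) {
  ci_t <- ci95(test_mean, test_sd, se_based, n_test)
  ci_r <- ci95(ref_mean, ref_sd, se_based, n_ref)
  data.frame(sample_id = sample_id,
             test_mean = test_mean, test_sd = test_sd,
             ref_mean = ref_mean, ref_sd = ref_sd,
             ci_test_lo = ci_t[1], ci_test_hi = ci_t[2],
             ci_ref_lo = ci_r[1], ci_ref_hi = ci_r[2],
             overlap = intervals_overlap(ci_t, ci_r),
             normalized = test_mean / ref_mean,
             percent_diff = abs(test_mean - ref_mean) / ref_mean * 100)
}
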