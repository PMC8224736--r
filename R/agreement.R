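# Method-comparison statistics: Bland-Altman bias and limits of agreement
# with 95% CIs, precision (2*SD/mean*100%), P30/P10 accuracy and ratio
# summaries.

#' Bland-Altman analysis
#'
#' Differences are oriented `d = ref - est` (positive bias means the
#' estimate runs low). Reports the mean difference (bias), SD of the
#' differences, limits of agreement `bias +/- 1.96 * SD`, 95% CIs of the
#' bias (t-based, `SD/sqrt(n)`) and of each limit (Bland & Altman's
#' `SD * sqrt(3/n)` approximation), and the precision of agreement
#' `2 * SD(d) / grand mean * 100` where the grand mean averages the
#' per-pair means `(ref + est)/2`.
#'
#' @param ref reference values (mL/min).
#' @param est estimated values (mL/min), same length, n >= 3.
#' @param conf confidence level for the CIs.
#' @return An object of class `bland_altman`: `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`,
#'   `precision_of_agreement`, `n`, and a `data` frame of per-pair means
#'   and differences for plotting.
#' @examples
#' bland_altman(c(10, 20, 30), c(11, 19, 31))
#' @export
bland_altman <- function(ref, est, conf = 0.95) {
  if (length(ref) != length(est)) stopf("ref and est lengths differ")
  n <- length(ref)
  if (n < 3) stopf("Bland-Altman analysis needs n >= 3 pairs")
  d <- ref - est
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_diff
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  grand_mean <- mean((ref + est) / 2)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_lower = loa[1], loa_upper = loa[2],
         ci_bias = bias + c(-1, 1) * tq * se_bias,
         ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
         ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa,
         precision_of_agreement = 2 * sd_diff / grand_mean * 100,
         n = n,
         data = data.frame(mean = (ref + est) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f +/- %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd_diff, x$loa_lower, x$loa_upper))
  cat(sprintf("  95%% CI bias [%.3f, %.3f]; precision of agreement %.1f%%\n",
              x$ci_bias[1], x$ci_bias[2], x$precision_of_agreement))
  invisible(x)
}

#' Precision of a method
#'
#' `2 * sample SD / mean * 100`, the dispersion of one method's estimates
#' across occasions expressed as a percentage of their mean. Scale
#' invariant. Distinct from the Bland-Altman precision of agreement, which
#' divides the SD of between-method differences by the grand mean.
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return Precision in percent.
#' @examples
#' precision_metric(c(8, 12))  # 56.57
#' @export
precision_metric <- function(values) {
  if (length(values) < 2) stopf("precision needs n >= 2")
  m <- mean(values)
  if (m == 0) stopf("undefined-precision: mean is zero")
  2 * stats::sd(values) / m * 100
}

#' Percentage of estimates within a relative tolerance of the reference
#'
#' `P30` is `p_within(ref, est, 0.30)`, `P10` is
#' `p_within(ref, est, 0.10)`. The boundary is inclusive:
#' `|est - ref| / ref <= tolerance` counts as within.
#'
#' @param ref reference values (all > 0).
#' @param est estimates, same length.
#' @param tolerance relative tolerance as a fraction (e.g. 0.30).
#' @return Percentage in `[0, 100]`.
#' @examples
#' p_within(c(10, 10), c(13, 14), 0.30)  # 50
#' @export
p_within <- function(ref, est, tolerance) {
  if (length(ref) != length(est)) stopf("ref and est lengths differ")
  if (any(ref <= 0)) stopf("reference values must be strictly positive")
  100 * mean(abs(est - ref) / ref <= tolerance)
}

#' Mean and SD of per-pair reference/estimate ratios
#'
#' @param ref reference values.
#' @param est estimates (all > 0), same length.
#' @return Named numeric `c(mean, sd)` of `ref / est`.
#' @examples
#' ratio_stats(c(10, 20), c(8, 25))  # mean 1.025, sd 0.3182
#' @export
ratio_stats <- function(ref, est) {
  if (length(ref) != length(est)) stopf("ref and est lengths differ")
  if (any(est <= 0)) stopf("estimates must be strictly positive")
  r <- ref / est
  c(mean = mean(r), sd = stats::sd(r))
}

#' Full agreement summary between a reference and an estimated method
#'
#' Bundles the Bland-Altman analysis with per-method precisions, P30/P10
#' accuracy and the ratio summary.
#'
#' @param ref reference values (mL/min), all > 0.
#' @param est estimates (mL/min), all > 0, same length, n >= 3.
#' @return An object of class `agreement_summary` with fields
#'   `bland_altman`, `precision_ref`, `precision_est`, `p30`, `p10`,
#'   `ratio_mean`, `ratio_sd`, `n`.
#' @export
agreement_summary <- function(ref, est) {
  ba <- bland_altman(ref, est)
  rs <- ratio_stats(ref, est)
  structure(
    list(bland_altman = ba,
         precision_ref = precision_metric(ref),
         precision_est = precision_metric(est),
         p30 = p_within(ref, est, 0.30),
         p10 = p_within(ref, est, 0.10),
         ratio_mean = unname(rs["mean"]),
         ratio_sd = unname(rs["sd"]),
         n = length(ref)),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  print(x$bland_altman)
  cat(sprintf("  precision ref %.1f%%, est %.1f%%; P30 %.0f%%, P10 %.0f%%\n",
              x$precision_ref, x$precision_est, x$p30, x$p10))
  cat(sprintf("  ratio ref/est: %.3f +/- %.3f\n", x$ratio_mean, x$ratio_sd))
  invisible(x)
}
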