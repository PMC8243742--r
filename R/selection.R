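#' Two-sided variance-ratio (F) test from arm summaries
#'
#' Tests equality of the two arms' variances with
#' `F = s_t^2 / s_c^2` on `(n_t - 1, n_c - 1)` degrees of freedom; the
#' two-sided p-value doubles the smaller tail, capped at 1, so it is
#' invariant to swapping the arms.
#'
#' @param t,c [arm_summary()] objects.
#' @return the two-sided p-value.
#' @examples
#' variance_ratio_test(arm_summary(31, 0, 2), arm_summary(31, 0, 1))
#' @export
variance_ratio_test <- function(t, c) {
  stop_if_degenerate(t, c)
  stopifnot(t$n >= 2, c$n >= 2)
  f <- t$sd^2 / c$sd^2
  lo <- stats::pf(f, t$n - 1, c$n - 1)
  hi <- stats::pf(f, t$n - 1, c$n - 1, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Glass's delta standardised effect size
#'
#' `Delta = (mean_t - mean_c) / s_c`: the between-arm mean difference
#' scaled by the control arm's SD, the appropriate standardisation when
#' variances may differ. Effect sizes with `|Delta|` above 0.75 are
#' treated as large by the automated procedure, triggering the
#' unequal-variance correction flag.
#'
#' @param t,c [arm_summary()] objects.
#' @return Glass's delta.
#' @export
glass_delta <- function(t, c) {
  if (c$sd <= 0) stop("Glass's delta requires a positive control-arm SD",
                      call. = FALSE)
  (t$mean - c$mean) / c$sd
}

#' Automated selection of the distributional method
#'
#' The screening-scale decision rule for choosing among the three
#' distributional methods from the observed data, when the population
#' distribution of each outcome is unknown:
#' \enumerate{
#'   \item if the skewness statistic is `<= -skew_cut` or `>= skew_cut`
#'     (default 1), use the skew-normal method;
#'   \item otherwise run the variance-ratio test: `p < var_alpha`
#'     (default 0.05) selects the normal method with unequal variances;
#'   \item otherwise (`p >= var_alpha`) the normal method with equal
#'     variances.
#' }
#' In addition, a standardised effect size (Glass's delta) above
#' `effect_cut` (default 0.75) marks the comparison as a large effect, for
#' which the unequal-variance standard error should carry a correction.
#' By default the skewness statistic is the per-arm skewness largest in
#' absolute value; a pre-computed statistic (e.g. pooled model-residual
#' skewness) can be supplied via `skewness_used`.
#'
#' Repeated use across many outcomes over-identifies skew-normal and
#' unequal-variance cases (each gate is itself a test); callers screening
#' many outcomes should review the selection tally the pipeline reports,
#' and equal variance is the recommended assumption when uncertain — the
#' boundary `p = var_alpha` therefore selects equal variances.
#'
#' @param t,c [arm_summary()] objects.
#' @param skew_cut skewness gate (default 1).
#' @param var_alpha variance-ratio test level (default 0.05).
#' @param effect_cut large-effect cutoff on |Glass's delta| (default 0.75).
#' @param skewness_used optional pre-computed skewness statistic
#'   overriding the per-arm maximum.
#' @return a `method_choice`: list with `method` (one of `"normal_equal"`,
#'   `"normal_unequal"`, `"skew_normal"`), `skewness_used`,
#'   `variance_test_p` (`NA` when the skew-normal branch is taken),
#'   `glass_delta`, `large_effect` and `rationale` (the ordered rule
#'   firings).
#' @export
select_method <- function(t, c, skew_cut = 1, var_alpha = 0.05,
                          effect_cut = 0.75, skewness_used = NULL) {
  stop_if_degenerate(t, c)
  if (is.null(skewness_used)) {
    sk <- c(t$skewness, c$skewness)
    skewness_used <- sk[which.max(abs(sk))]
  }
  delta <- glass_delta(t, c)
  large <- abs(delta) > effect_cut
  rationale <- character()
  if (abs(skewness_used) >= skew_cut) {
    method <- "skew_normal"
    var_p <- NA_real_
    rationale <- c(rationale, sprintf(
      "|skewness| = %.3f >= %.3g: skew-normal method", abs(skewness_used),
      skew_cut))
  } else {
    rationale <- c(rationale, sprintf(
      "|skewness| = %.3f < %.3g: normal family", abs(skewness_used),
      skew_cut))
    var_p <- variance_ratio_test(t, c)
    if (var_p < var_alpha) {
      method <- "normal_unequal"
      rationale <- c(rationale, sprintf(
        "variance-ratio p = %.4f < %.3g: unequal variances", var_p,
        var_alpha))
    } else {
      method <- "normal_equal"
      rationale <- c(rationale, sprintf(
        "variance-ratio p = %.4f >= %.3g: equal variances", var_p,
        var_alpha))
    }
  }
  rationale <- c(rationale, sprintf(
    "|Glass's delta| = %.3f %s %.3g: %slarge effect", abs(delta),
    if (large) ">" else "<=", effect_cut, if (large) "" else "not a "))
  structure(list(method = method, skewness_used = skewness_used,
                 variance_test_p = var_p, glass_delta = delta,
                 large_effect = large, rationale = rationale),
            class = "method_choice")
}

#' @export
print.method_choice <- function(x, ...) {
  cat("automated method choice:", x$method, "\n")
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' Dispatch the selected unadjusted distributional method
#'
#' Convenience wrapper: runs [select_method()] and then the chosen
#' unadjusted comparison, applying the large-effect correction multiplier
#' to the unequal-variance method when flagged.
#'
#' @inheritParams select_method
#' @inheritParams diff_unequal_variance
#' @param threshold,tail,level passed to the chosen method.
#' @return a `prop_comparison` whose `details$choice` is the
#'   `method_choice`.
#' @export
diff_auto <- function(t, c, threshold, tail = c("below", "above"),
                      correction = 1, level = 0.95, ...) {
  tail <- match.arg(tail)
  choice <- select_method(t, c, ...)
  cmp <- switch(choice$method,
    skew_normal = diff_skew_normal(t, c, threshold, tail, level),
    normal_unequal = diff_unequal_variance(
      t, c, threshold, tail, R = NULL, correction = correction,
      large_effect = choice$large_effect, level = level),
    normal_equal = diff_equal_variance(t, c, threshold, tail, level))
  cmp$details$choice <- choice
  cmp
}
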