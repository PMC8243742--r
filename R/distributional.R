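#' Wald interval and two-sided p-value
#'
#' Common tail machinery for all delta-method comparisons: a symmetric
#' normal-theory interval `d +/- z * se` and the two-sided p-value of
#' `|d / se|` against a standard normal. A zero standard error with a zero
#' estimate is reported as degenerate with `p = 1` (no information, no
#' spurious certainty); a zero standard error with a non-zero estimate is
#' an error.
#'
#' @param d point estimate.
#' @param se standard error, `>= 0`.
#' @param level two-sided coverage, in (0, 1).
#' @return list with `ci_low`, `ci_high`, `p_value`, `degenerate`.
#' @export
wald_interval_and_p <- function(d, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  if (se == 0) {
    if (d != 0) {
      stop("degenerate comparison: zero standard error with non-zero estimate",
           call. = FALSE)
    }
    return(list(ci_low = 0, ci_high = 0, p_value = 1, degenerate = TRUE))
  }
  z <- stats::qnorm((1 + level) / 2)
  list(ci_low = d - z * se, ci_high = d + z * se,
       p_value = 2 * stats::pnorm(-abs(d / se)), degenerate = FALSE)
}

new_prop_comparison <- function(d, se, method, level = 0.95,
                                flags = character(), details = list()) {
  w <- wald_interval_and_p(d, se, level)
  if (w$degenerate) flags <- union(flags, "degenerate")
  structure(list(d = d, se = se, ci_low = w$ci_low, ci_high = w$ci_high,
                 p_value = w$p_value, level = level, method = method,
                 flags = flags, details = details),
            class = "prop_comparison")
}

#' @export
print.prop_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("difference in proportions (%s): %.*f [%.*f, %.*f], p = %s\n",
              x$method, digits, x$d, digits, x$ci_low, digits, x$ci_high,
              format_p(x$p_value)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

stop_if_degenerate <- function(...) {
  for (s in list(...)) {
    if (isTRUE(s$zero_variance) || s$sd <= 0) {
      stop("degenerate distribution: zero variance in an arm; ",
           "distributional methods require sd > 0", call. = FALSE)
    }
  }
}

pooled_sd <- function(t, c) {
  sqrt(((t$n - 1) * t$sd^2 + (c$n - 1) * c$sd^2) / (t$n + c$n - 2))
}

#' Distributional proportion beyond a threshold, normal model
#'
#' Estimates the proportion of a population below (or above) a threshold
#' from the fitted normal distribution of a continuous outcome:
#' `p = Phi((x0 - mean) / s)` for the lower tail, with delta-method
#' standard error `se(p) = (s / sqrt(n)) * f(x0)` where `f` is the normal
#' density with the arm's mean and variance `s^2`. This is what lets a
#' comparison of proportions inherit the precision of a comparison of
#' means, including with zero observed events.
#'
#' @param summary an [arm_summary()].
#' @param threshold abnormality threshold `x0` (outcome units).
#' @param tail `"below"` or `"above"`.
#' @param sd_override use this SD instead of the arm's own (e.g. a pooled
#'   or unequal-variance adjusted SD).
#' @return a `prop_estimate`: list with `p`, `se`, `threshold`, `tail`,
#'   `method`.
#' @examples
#' normal_proportion(arm_summary(100, 0, 1), threshold = 0, tail = "below")
#' @export
normal_proportion <- function(summary, threshold, tail = c("below", "above"),
                              sd_override = NULL) {
  tail <- match.arg(tail)
  s <- if (is.null(sd_override)) summary$sd else sd_override
  if (!is.finite(s) || s <= 0) {
    stop("degenerate distribution: zero or invalid standard deviation",
         call. = FALSE)
  }
  stopifnot(summary$n >= 2)
  p_below <- stats::pnorm((threshold - summary$mean) / s)
  p <- if (tail == "below") p_below else 1 - p_below
  se <- (s / sqrt(summary$n)) * stats::dnorm(threshold, summary$mean, s)
  structure(list(p = p, se = se, threshold = threshold, tail = tail,
                 method = "normal"),
            class = "prop_estimate")
}

#' Distributional difference in proportions, equal variances
#'
#' The normal distributional method for two arms sharing a common variance:
#' each arm's proportion beyond the threshold is computed from its mean and
#' the pooled SD, and the standard error of the difference is
#' `sqrt(s^2/n_t * f_t(x0)^2 + s^2/n_c * f_c(x0)^2)` with `f_t`, `f_c` the
#' normal densities at the threshold under each arm's mean and the pooled
#' variance (per-arm sample sizes are used so unequal arms are handled; with
#' equal arms this is the single-n textbook form).
#'
#' @param t,c [arm_summary()] for the treatment and control arm.
#' @inheritParams normal_proportion
#' @param level two-sided confidence level.
#' @return a `prop_comparison` with `d = p_t - p_c`, `se`, Wald interval and
#'   p-value; `details` holds the pooled SD and per-arm proportions.
#' @export
diff_equal_variance <- function(t, c, threshold, tail = c("below", "above"),
                                level = 0.95) {
  tail <- match.arg(tail)
  stop_if_degenerate(t, c)
  s <- pooled_sd(t, c)
  et <- normal_proportion(t, threshold, tail, sd_override = s)
  ec <- normal_proportion(c, threshold, tail, sd_override = s)
  se <- sqrt(et$se^2 + ec$se^2)
  new_prop_comparison(et$p - ec$p, se, "normal_equal", level,
                      details = list(s = s, p_t = et$p, p_c = ec$p))
}

#' Distributional difference in proportions, unequal variances
#'
#' When treatment inflates (or deflates) outcome variability, the pooled
#' estimate is adjusted by the variance ratio `R = sigma_t^2 / sigma_c^2`:
#' `s_uneq = sqrt(((n_t-1) s_t^2 + (n_c-1) R s_c^2) / (n_t + n_c - 2))`,
#' the treatment arm's proportion uses variance `s_uneq^2` and the control
#' arm's uses `(s_uneq / sqrt(R))^2`, and the delta-method standard error
#' combines the two accordingly. `R` should ideally come from previous
#' studies; when absent it is estimated as `s_t^2 / s_c^2` from the
#' observed data, in which case the standard error is known to
#' underestimate the true variability for large effects and a correction
#' multiplier may be applied (see `correction`).
#'
#' @inheritParams diff_equal_variance
#' @param R variance ratio `sigma_t^2 / sigma_c^2`; `NULL` to estimate from
#'   the observed SDs.
#' @param correction standard-error multiplier applied when `large_effect`
#'   is `TRUE` (default 1, i.e. no correction); see the package vignette
#'   for guidance on choosing a validated value.
#' @param large_effect set by the caller when the standardised effect size
#'   (Glass's delta) exceeds the large-effect cutoff.
#' @return a `prop_comparison`; `details` holds `s_uneq` and `R`, and
#'   `flags` record whether `R` was estimated and whether the correction
#'   was applied.
#' @export
diff_unequal_variance <- function(t, c, threshold, tail = c("below", "above"),
                                  R = NULL, correction = 1,
                                  large_effect = FALSE, level = 0.95) {
  tail <- match.arg(tail)
  stop_if_degenerate(t, c)
  flags <- character()
  if (is.null(R)) {
    R <- t$sd^2 / c$sd^2
    flags <- c(flags, "R_estimated")
  } else {
    if (R <= 0) stop("variance ratio R must be positive", call. = FALSE)
    flags <- c(flags, "R_supplied")
  }
  s_uneq <- sqrt(((t$n - 1) * t$sd^2 + (c$n - 1) * R * c$sd^2) /
                   (t$n + c$n - 2))
  s_ctrl <- s_uneq / sqrt(R)
  et <- normal_proportion(t, threshold, tail, sd_override = s_uneq)
  ec <- normal_proportion(c, threshold, tail, sd_override = s_ctrl)
  se <- sqrt(et$se^2 + ec$se^2)
  if (isTRUE(large_effect)) {
    flags <- c(flags, "large_effect")
    se <- se * correction
    if (correction != 1) flags <- c(flags, "correction_applied")
  }
  new_prop_comparison(et$p - ec$p, se, "normal_unequal", level, flags = flags,
                      details = list(s_uneq = s_uneq, R = R,
                                     p_t = et$p, p_c = ec$p,
                                     correction = correction))
}

#' Fit a skew-normal to an arm summary
#'
#' Method-of-moments skew-normal fit from an arm's mean, SD and skewness;
#' see [sn_from_moments()] for the clamping of skewness to the family's
#' attainable range.
#'
#' @param summary an [arm_summary()].
#' @return an `sn_params` object.
#' @export
fit_skew_normal <- function(summary) {
  stop_if_degenerate(summary)
  sn_from_moments(summary$mean, summary$sd, summary$skewness)
}

#' Distributional proportion beyond a threshold, skew-normal model
#'
#' As [normal_proportion()] but for a skewed outcome: `p` is the
#' skew-normal distribution function at the threshold (or its complement),
#' and the delta-method standard error perturbs the location parameter
#' only, `se(p) = (sample_sd / sqrt(n)) * f_sn(x0)` with `f_sn` the fitted
#' skew-normal density.
#'
#' @param params an `sn_params` object from [fit_skew_normal()].
#' @param n arm sample size.
#' @param sample_sd the arm's sample SD (outcome units).
#' @inheritParams normal_proportion
#' @return a `prop_estimate` with `method = "skew_normal"`.
#' @export
skew_normal_proportion <- function(params, n, sample_sd, threshold,
                                   tail = c("below", "above")) {
  tail <- match.arg(tail)
  stopifnot(n >= 2, sample_sd > 0)
  p_below <- psn(threshold, params$xi, params$omega, params$alpha)
  p <- if (tail == "below") p_below else 1 - p_below
  se <- (sample_sd / sqrt(n)) * dsn(threshold, params$xi, params$omega,
                                    params$alpha)
  structure(list(p = p, se = se, threshold = threshold, tail = tail,
                 method = "skew_normal"),
            class = "prop_estimate")
}

#' Distributional difference in proportions, skew-normal model
#'
#' Fits a skew-normal to each arm by the method of moments and contrasts
#' the implied proportions beyond the threshold;
#' `se(d) = sqrt(se_t^2 + se_c^2)` from the per-arm delta-method standard
#' errors. With small skewness this agrees closely with the normal method.
#'
#' @inheritParams diff_equal_variance
#' @return a `prop_comparison` with `method = "skew_normal"`; `flags`
#'   carry `skewness_clamped` if either arm's skewness exceeded the
#'   attainable range, and `details` hold both fitted parameter sets.
#' @export
diff_skew_normal <- function(t, c, threshold, tail = c("below", "above"),
                             level = 0.95) {
  tail <- match.arg(tail)
  stop_if_degenerate(t, c)
  ft <- fit_skew_normal(t)
  fc <- fit_skew_normal(c)
  et <- skew_normal_proportion(ft, t$n, t$sd, threshold, tail)
  ec <- skew_normal_proportion(fc, c$n, c$sd, threshold, tail)
  flags <- character()
  if (isTRUE(ft$clamped) || isTRUE(fc$clamped)) {
    flags <- c(flags, "skewness_clamped")
  }
  new_prop_comparison(et$p - ec$p, sqrt(et$se^2 + ec$se^2), "skew_normal",
                      level, flags = flags,
                      details = list(params_t = ft, params_c = fc,
                                     p_t = et$p, p_c = ec$p))
}
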