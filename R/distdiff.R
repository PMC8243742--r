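#' Distributional difference in proportions beyond a threshold
#'
#' The package's central fitting function. Given subject-level data from a
#' two-arm trial, estimates the between-arm difference in the proportion
#' of the population with outcome values beyond an abnormality threshold,
#' using fitted distribution parameters rather than observed event counts
#' — so the comparison of proportions retains the precision of a
#' comparison of means, and remains estimable even with zero observed
#' events.
#'
#' The formula names the outcome and the arm, e.g. `value ~ arm`; any
#' further right-hand-side terms are adjustment covariates, which switch
#' the fit to the covariate-adjusted pathway (marginal means from a
#' linear or random-intercept model, residual-distribution proportions).
#' `method = "auto"` applies the automated selection procedure: the
#' skew-normal method when the observed |skewness| is 1 or more, else the
#' normal method with unequal variances when a variance-ratio test
#' rejects at the 5% level, else the normal method with equal variances;
#' in the adjusted pathway the same skewness gate chooses the residual
#' family (the unequal-variance method is unadjusted-only, so when it is
#' selected alongside covariates the unadjusted estimate is reported and
#' a warning notes the fallback for adjusted columns).
#'
#' @param formula `outcome ~ arm` or `outcome ~ arm + covariates`; the arm
#'   variable must take exactly two values.
#' @param data a data.frame (one row per subject).
#' @param threshold abnormality threshold `x0` (outcome units).
#' @param tail `"below"` (abnormally low) or `"above"` (abnormally high).
#' @param method `"auto"` (default), `"normal_equal"`, `"normal_unequal"`,
#'   `"skew_normal"` or `"empirical"` (the dichotomised Wald comparator).
#' @param arm_levels length-2 character vector `c(control, treatment)`;
#'   defaults to sorted order.
#' @param level two-sided confidence level.
#' @param R variance ratio for the unequal-variance method (`NULL`:
#'   estimate from the data).
#' @param correction large-effect standard-error correction multiplier for
#'   the unequal-variance method.
#' @param random_intercept optional grouping column name for a
#'   random-intercept model.
#' @param ... passed to [select_method()] (`skew_cut`, `var_alpha`,
#'   `effect_cut`).
#' @return an object of class `distdiff`: the fitted comparison with
#'   `print`, `summary`, `coef` and `confint` methods. Components include
#'   `comparison` (a `prop_comparison`), `choice` (the `method_choice`
#'   when `method = "auto"`), `counts` (observed abnormal counts) and
#'   `fit` (the adjusted model, when covariates are used).
#' @examples
#' set.seed(1)
#' d <- data.frame(arm = rep(c("placebo", "active"), each = 80),
#'                 value = rnorm(160, mean = rep(c(0, 0.4), each = 80)))
#' distdiff(value ~ arm, d, threshold = -1.645, tail = "below",
#'          arm_levels = c("placebo", "active"))
#' @export
distdiff <- function(formula, data, threshold, tail = c("below", "above"),
                     method = c("auto", "normal_equal", "normal_unequal",
                                "skew_normal", "empirical"),
                     arm_levels = NULL, level = 0.95, R = NULL,
                     correction = 1, random_intercept = NULL, ...) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  vars <- all.vars(formula)
  outcome_var <- vars[1]
  arm_var <- vars[2]
  covariates <- vars[-(1:2)]
  stopifnot(all(vars %in% names(data)))
  arm <- as.character(data[[arm_var]])
  y <- data[[outcome_var]]
  if (is.null(arm_levels)) arm_levels <- sort(unique(arm))
  if (length(arm_levels) != 2L || !setequal(arm_levels, unique(arm))) {
    stop("data error: arm variable must take exactly the two arm_levels",
         call. = FALSE)
  }
  y_c <- y[arm == arm_levels[1]]
  y_t <- y[arm == arm_levels[2]]
  counts <- dichotomise(y_t, y_c, threshold, tail)
  sum_t <- summarize_arm(y_t)
  sum_c <- summarize_arm(y_c)
  choice <- NULL
  fit <- NULL
  adjusted <- length(covariates) > 0 || !is.null(random_intercept)
  if (method == "empirical") {
    cmp <- empirical_diff_proportions(counts, level)
  } else if (!adjusted) {
    cmp <- switch(method,
      auto = {
        choice <- select_method(sum_t, sum_c, ...)
        out <- diff_auto(sum_t, sum_c, threshold, tail,
                         correction = correction, level = level, ...)
        out
      },
      normal_equal = diff_equal_variance(sum_t, sum_c, threshold, tail,
                                         level),
      normal_unequal = diff_unequal_variance(
        sum_t, sum_c, threshold, tail, R = R, correction = correction,
        large_effect = abs(glass_delta(sum_t, sum_c)) > 0.75,
        level = level),
      skew_normal = diff_skew_normal(sum_t, sum_c, threshold, tail, level))
    if (!is.null(cmp$details$choice)) choice <- cmp$details$choice
  } else {
    df <- data.frame(value = y, arm = arm, data[, c(covariates,
                                                    random_intercept),
                                                drop = FALSE])
    fit <- fit_adjusted_model(df, covariates = covariates,
                              random_intercept = random_intercept,
                              arm_levels = arm_levels)
    family <- "normal"
    if (method == "auto") {
      choice <- select_method(sum_t, sum_c, ...)
      if (choice$method == "skew_normal") {
        family <- "skew_normal"
      } else if (choice$method == "normal_unequal") {
        warning("unequal variances selected: reporting the unadjusted ",
                "unequal-variance estimate (covariate adjustment supports ",
                "normal and skew-normal residuals only)", call. = FALSE)
        cmp <- diff_unequal_variance(sum_t, sum_c, threshold, tail,
                                     R = NULL, correction = correction,
                                     large_effect = choice$large_effect,
                                     level = level)
        cmp$details$choice <- choice
        return(new_distdiff(cmp, choice, counts, fit, threshold, tail,
                            arm_levels, match.call()))
      }
    } else if (method == "skew_normal") {
      family <- "skew_normal"
    } else if (method == "normal_unequal") {
      stop("the unequal-variance method does not support covariate ",
           "adjustment; fit it without covariates", call. = FALSE)
    }
    cmp <- adjusted_distributional_difference(fit, threshold, tail,
                                              residual_family = family,
                                              level = level)
  }
  new_distdiff(cmp, choice, counts, fit, threshold, tail, arm_levels,
               match.call())
}

new_distdiff <- function(cmp, choice, counts, fit, threshold, tail,
                         arm_levels, call) {
  structure(list(comparison = cmp, choice = choice, counts = counts,
                 fit = fit, threshold = threshold, tail = tail,
                 arm_levels = arm_levels, call = call),
            class = "distdiff")
}

#' @export
print.distdiff <- function(x, digits = 3, ...) {
  cat("distributional difference in proportions", sprintf(
    "(%s threshold %s, %s method)\n", x$tail, format(x$threshold),
    x$comparison$method))
  cat(sprintf("  observed abnormal: %s %d/%d, %s %d/%d\n",
              x$arm_levels[2], x$counts$events_t, x$counts$n_t,
              x$arm_levels[1], x$counts$events_c, x$counts$n_c))
  cat(sprintf("  d = %.*f [%.*f, %.*f], se = %.*f, p = %s\n", digits,
              x$comparison$d, digits, x$comparison$ci_low, digits,
              x$comparison$ci_high, digits, x$comparison$se,
              format_p(x$comparison$p_value)))
  if (length(x$comparison$flags)) {
    cat("  flags:", paste(x$comparison$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.distdiff <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$choice)) print(object$choice)
  if (!is.null(object$fit)) print(object$fit)
  invisible(object)
}

#' @export
coef.distdiff <- function(object, ...) {
  c(difference = object$comparison$d)
}

#' @export
confint.distdiff <- function(object, parm, level = NULL, ...) {
  cmp <- object$comparison
  if (!is.null(level) && level != cmp$level) {
    w <- wald_interval_and_p(cmp$d, cmp$se, level)
    ci <- c(w$ci_low, w$ci_high)
  } else {
    level <- cmp$level
    ci <- c(cmp$ci_low, cmp$ci_high)
  }
  m <- matrix(ci, nrow = 1,
              dimnames = list("difference",
                              sprintf("%.1f %%",
                                      c((1 - level) / 2,
                                        (1 + level) / 2) * 100)))
  m
}
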