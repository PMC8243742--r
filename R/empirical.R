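#' Dichotomise continuous values at an abnormality threshold
#'
#' The standard-practice comparator step: counts of participants with
#' abnormal values in each arm. Abnormality uses strict inequalities —
#' below counts values strictly less than the threshold, above strictly
#' greater — so a value exactly at a reference-range limit is normal
#' (reference ranges are inclusive normal ranges). Missing values are
#' excluded from numerator and denominator alike.
#'
#' @param values_t,values_c numeric vectors for the treatment and control
#'   arms.
#' @param threshold abnormality threshold (outcome units).
#' @param tail `"below"` or `"above"`.
#' @param strict use strict inequalities (default; set `FALSE` to count
#'   threshold-equal values as abnormal).
#' @return an `abnormal_counts`: list with `events_t`, `n_t`, `events_c`,
#'   `n_c`, `threshold`, `tail`.
#' @export
dichotomise <- function(values_t, values_c, threshold,
                        tail = c("below", "above"), strict = TRUE) {
  tail <- match.arg(tail)
  stopifnot(is.finite(threshold))
  values_t <- values_t[!is.na(values_t)]
  values_c <- values_c[!is.na(values_c)]
  if (!length(values_t) || !length(values_c)) {
    stop("no analysable data: an arm has no non-missing values",
         call. = FALSE)
  }
  hit <- function(v) {
    if (tail == "below") {
      if (strict) v < threshold else v <= threshold
    } else {
      if (strict) v > threshold else v >= threshold
    }
  }
  abnormal_counts(sum(hit(values_t)), length(values_t),
                  sum(hit(values_c)), length(values_c),
                  threshold = threshold, tail = tail)
}

#' @rdname dichotomise
#' @param events_t,n_t,events_c,n_c construct counts directly (e.g. from a
#'   published table).
#' @export
abnormal_counts <- function(events_t, n_t, events_c, n_c,
                            threshold = NA_real_,
                            tail = c("below", "above")) {
  tail <- match.arg(tail)
  stopifnot(events_t >= 0, events_c >= 0, events_t <= n_t, events_c <= n_c)
  structure(list(events_t = events_t, n_t = n_t,
                 events_c = events_c, n_c = n_c,
                 threshold = threshold, tail = tail),
            class = "abnormal_counts")
}

#' @export
print.abnormal_counts <- function(x, ...) {
  cat(sprintf("abnormal (%s %s): treatment %d/%d, control %d/%d\n",
              x$tail, format(x$threshold), x$events_t, x$n_t,
              x$events_c, x$n_c))
  invisible(x)
}

#' Fisher's exact test for a 2x2 abnormality table
#'
#' Two-sided exact test comparing the proportions of abnormal values
#' between arms. The default convention sums the hypergeometric point
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one — the convention of the major
#' statistical environments; `convention = "doubling"` instead doubles
#' the smaller one-sided tail (capped at 1), which some packages use and
#' which yields slightly larger p-values for asymmetric margins. When
#' both arms have zero events the comparison is non-estimable and `NA` is
#' returned (reported as `NE` downstream, never counted as a signal).
#'
#' @param counts an [abnormal_counts()] object.
#' @param convention `"min_likelihood"` (default) or `"doubling"`.
#' @return the two-sided p-value, or `NA_real_` when non-estimable.
#' @export
fisher_exact <- function(counts, convention = c("min_likelihood", "doubling")) {
  convention <- match.arg(convention)
  if (counts$events_t == 0 && counts$events_c == 0) {
    return(NA_real_)
  }
  m1 <- counts$events_t + counts$events_c
  x_obs <- counts$events_t
  support <- max(0, m1 - counts$n_c):min(m1, counts$n_t)
  prob <- stats::dhyper(support, counts$n_t, counts$n_c, m1)
  p_obs <- stats::dhyper(x_obs, counts$n_t, counts$n_c, m1)
  if (convention == "min_likelihood") {
    p <- sum(prob[prob <= p_obs * (1 + 1e-7)])
  } else {
    lo <- sum(prob[support <= x_obs])
    hi <- sum(prob[support >= x_obs])
    p <- 2 * min(lo, hi)
  }
  min(1, p)
}

#' Empirical (Wald) difference in proportions
#'
#' The standard asymptotic comparator: `d = p_t - p_c` from the observed
#' event proportions with unpooled standard error
#' `sqrt(p_t (1 - p_t) / n_t + p_c (1 - p_c) / n_c)` and no continuity
#' correction. With zero events in both arms this construction reports a
#' difference of exactly 0 with a zero-width interval — no uncertainty at
#' all, which is incorrect; the result carries a `degenerate` flag to make
#' that visible (the distributional methods remain estimable in this
#' case).
#'
#' @param counts an [abnormal_counts()] object.
#' @param level two-sided confidence level.
#' @return a `prop_comparison` with `method = "empirical"`.
#' @export
empirical_diff_proportions <- function(counts, level = 0.95) {
  pt <- counts$events_t / counts$n_t
  pc <- counts$events_c / counts$n_c
  d <- pt - pc
  se <- sqrt(pt * (1 - pt) / counts$n_t + pc * (1 - pc) / counts$n_c)
  details <- list(p_t = pt, p_c = pc, counts = counts)
  if (se == 0 && d != 0) {
    # all-events-vs-no-events tables: the Wald construction reports no
    # uncertainty at all; surface the estimate but flag it
    return(structure(list(d = d, se = 0, ci_low = d, ci_high = d,
                          p_value = NA_real_, level = level,
                          method = "empirical", flags = "degenerate",
                          details = details),
                     class = "prop_comparison"))
  }
  new_prop_comparison(d, se, "empirical", level, details = details)
}

#' Count signals across a screen's results
#'
#' Per-criterion tallies of outcomes flagged at the given level: Fisher
#' p-values below `alpha` (non-estimable results never count), regression
#' and distributional p-values below `alpha`, and empirical Wald intervals
#' excluding zero (degenerate zero-width intervals never count). Inputs
#' are vectors/lists aligned across outcomes; any component may be
#' omitted.
#'
#' @param fisher_p numeric vector of Fisher p-values (`NA` = NE).
#' @param empirical list of `prop_comparison` objects (empirical method).
#' @param regression_p numeric vector of regression treatment-coefficient
#'   p-values.
#' @param distributional_p numeric vector of distributional p-values.
#' @param alpha signal level (default 0.05).
#' @return named integer vector of per-criterion signal counts.
#' @export
count_signals <- function(fisher_p = NULL, empirical = NULL,
                          regression_p = NULL, distributional_p = NULL,
                          alpha = 0.05) {
  out <- integer()
  if (!is.null(fisher_p)) {
    out["fisher"] <- sum(!is.na(fisher_p) & fisher_p < alpha)
  }
  if (!is.null(empirical)) {
    ex <- vapply(empirical, function(e) {
      !("degenerate" %in% e$flags) && (e$ci_low > 0 || e$ci_high < 0)
    }, logical(1))
    out["empirical_ci"] <- sum(ex)
  }
  if (!is.null(regression_p)) {
    out["regression"] <- sum(!is.na(regression_p) & regression_p < alpha)
  }
  if (!is.null(distributional_p)) {
    out["distributional"] <- sum(!is.na(distributional_p) &
                                   distributional_p < alpha)
  }
  if (!length(out)) stop("no results supplied", call. = FALSE)
  out
}
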