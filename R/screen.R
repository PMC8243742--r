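#' Screen a trial's continuous safety outcomes for signals
#'
#' Runs the full per-outcome screen on a long-format trial dataset: for
#' every configured outcome and every available tail (abnormally low
#' values below the reference-range `low`, abnormally high above `high`),
#' at the endpoint visit, it computes (i) the empirical comparators —
#' abnormal counts, Fisher's exact test, Wald difference in proportions;
#' (ii) the covariate-adjusted mean difference from a linear model; and
#' (iii) the adjusted distributional difference in proportions, with the
#' distributional method chosen per outcome by the automated procedure.
#' Results are interpreted as signals for potential adverse drug
#' reactions to follow up, not confirmed effects; no multiplicity
#' adjustment is applied and the report states the number of tests
#' performed.
#'
#' When the automated procedure selects unequal variances, the
#' distributional columns carry the unadjusted unequal-variance estimate
#' (covariate adjustment composes only with normal or skew-normal
#' residuals) and a warning is issued. Outcomes with zero variance in an
#' arm keep their empirical columns but have non-estimable distributional
#' columns.
#'
#' @param dataset a `trial_dataset` from [read_lab_data()],
#'   [generate_trial()] or [as_trial_dataset()].
#' @param ranges list of [reference_range()] objects (or a path handled by
#'   [read_reference_ranges()]).
#' @param covariates character vector of covariate column names to adjust
#'   for (e.g. randomisation stratification variables).
#' @param visit `"last"` (last observed value per subject, the default
#'   endpoint) or a numeric week.
#' @param alpha signal level for the per-row signal flags.
#' @param correction large-effect standard-error multiplier for the
#'   unequal-variance method (default 1).
#' @param fisher_convention `"min_likelihood"` or `"doubling"`, see
#'   [fisher_exact()].
#' @param strict strict inequalities when dichotomising (default).
#' @param skewness_basis `"per_arm_max"` (default) or `"pooled_residual"`:
#'   the skewness statistic fed to the automated procedure.
#' @param arm_levels `c(control, treatment)`; defaults to the dataset's
#'   attribute or sorted order.
#' @param level confidence level for all intervals.
#' @return a `signal_table`: a data.frame with one row per outcome x tail
#'   (alphabetical by outcome), full-precision columns for every
#'   component, per-criterion signal flags, and attributes
#'   `method_tally`, `n_tests`, `alpha` and `arm_levels`.
#' @export
run_screen <- function(dataset, ranges, covariates = character(),
                       visit = "last", alpha = 0.05, correction = 1,
                       fisher_convention = c("min_likelihood", "doubling"),
                       strict = TRUE,
                       skewness_basis = c("per_arm_max", "pooled_residual"),
                       arm_levels = NULL, level = 0.95) {
  fisher_convention <- match.arg(fisher_convention)
  skewness_basis <- match.arg(skewness_basis)
  if (is.character(ranges) && length(ranges) == 1L) {
    ranges <- read_reference_ranges(ranges)
  }
  if (inherits(ranges, "reference_range")) ranges <- list(ranges)
  if (is.null(arm_levels)) arm_levels <- attr(dataset, "arm_levels")
  if (is.null(arm_levels)) {
    arm_levels <- sort(unique(as.character(dataset$arm)))
  }
  outcomes <- vapply(ranges, `[[`, character(1), "outcome")
  present <- unique(as.character(dataset$outcome))
  absent <- setdiff(outcomes, present)
  if (length(absent)) {
    stop("configuration error: outcome(s) not in dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cross <- select_endpoint_visit(dataset, visit)
  ord <- order(outcomes)
  ranges <- ranges[ord]
  rows <- list()
  for (rg in ranges) {
    oc <- cross[cross$outcome == rg$outcome, , drop = FALSE]
    arm <- as.character(oc$arm)
    y_c <- oc$value[arm == arm_levels[1]]
    y_t <- oc$value[arm == arm_levels[2]]
    sum_t <- summarize_arm(y_t)
    sum_c <- summarize_arm(y_c)
    degenerate_arm <- sum_t$zero_variance || sum_c$zero_variance
    fit <- NULL
    choice <- NULL
    if (!degenerate_arm) {
      fit <- fit_adjusted_model(oc, covariates = covariates,
                                arm_levels = arm_levels)
      sk <- if (skewness_basis == "pooled_residual") {
        fit$resid_skewness
      } else NULL
      choice <- select_method(sum_t, sum_c, skewness_used = sk)
    }
    tails <- c(if (!is.null(rg$low)) "below", if (!is.null(rg$high)) "above")
    for (tl in tails) {
      x0 <- if (tl == "below") rg$low else rg$high
      counts <- dichotomise(y_t, y_c, x0, tl, strict = strict)
      fp <- fisher_exact(counts, fisher_convention)
      emp <- empirical_diff_proportions(counts, level)
      if (degenerate_arm) {
        warning("outcome '", rg$outcome, "': zero variance in an arm; ",
                "distributional columns are non-estimable", call. = FALSE)
        dist <- NULL
      } else if (choice$method == "normal_unequal") {
        warning("outcome '", rg$outcome, "': unequal variances selected; ",
                "reporting the unadjusted unequal-variance estimate",
                call. = FALSE)
        dist <- diff_unequal_variance(sum_t, sum_c, x0, tl, R = NULL,
                                      correction = correction,
                                      large_effect = choice$large_effect,
                                      level = level)
      } else {
        fam <- if (choice$method == "skew_normal") "skew_normal" else
          "normal"
        dist <- adjusted_distributional_difference(fit, x0, tl,
                                                   residual_family = fam,
                                                   level = level)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = rg$outcome, tail = tl, threshold = x0,
        events_c = counts$events_c, n_c = counts$n_c,
        prop_c = counts$events_c / counts$n_c,
        events_t = counts$events_t, n_t = counts$n_t,
        prop_t = counts$events_t / counts$n_t,
        mean_diff = if (is.null(fit)) NA_real_ else fit$coef,
        mean_ci_low = if (is.null(fit)) NA_real_ else fit$coef_ci[1],
        mean_ci_high = if (is.null(fit)) NA_real_ else fit$coef_ci[2],
        mean_p = if (is.null(fit)) NA_real_ else fit$coef_p,
        dist_method = if (is.null(dist)) "NE" else dist$method,
        dist_d = if (is.null(dist)) NA_real_ else dist$d,
        dist_ci_low = if (is.null(dist)) NA_real_ else dist$ci_low,
        dist_ci_high = if (is.null(dist)) NA_real_ else dist$ci_high,
        dist_p = if (is.null(dist)) NA_real_ else dist$p_value,
        dist_flags = if (is.null(dist)) "" else
          paste(dist$flags, collapse = ";"),
        fisher_p = fp,
        emp_d = emp$d, emp_ci_low = emp$ci_low, emp_ci_high = emp$ci_high,
        emp_degenerate = "degenerate" %in% emp$flags,
        skewness_used = if (is.null(choice)) NA_real_ else
          choice$skewness_used,
        variance_p = if (is.null(choice)) NA_real_ else
          choice$variance_test_p,
        glass_delta = if (is.null(choice)) NA_real_ else
          choice$glass_delta,
        large_effect = if (is.null(choice)) NA else choice$large_effect,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$signal_fisher <- !is.na(tab$fisher_p) & tab$fisher_p < alpha
  tab$signal_empirical_ci <- !tab$emp_degenerate &
    (tab$emp_ci_low > 0 | tab$emp_ci_high < 0)
  tab$signal_regression <- !is.na(tab$mean_p) & tab$mean_p < alpha
  tab$signal_distributional <- !is.na(tab$dist_p) & tab$dist_p < alpha
  tally <- table(factor(tab$dist_method[!duplicated(tab$outcome)],
                        levels = c("normal_equal", "adjusted_normal",
                                   "normal_unequal", "skew_normal",
                                   "adjusted_skew_normal", "NE")))
  structure(tab, class = c("signal_table", "data.frame"),
            method_tally = tally, n_tests = nrow(tab), alpha = alpha,
            arm_levels = arm_levels, level = level)
}

#' Signal counts of a screen
#'
#' Applies [count_signals()] to a `signal_table`.
#'
#' @param table a `signal_table`.
#' @param alpha signal level; defaults to the table's.
#' @return named integer vector of per-criterion signal counts.
#' @export
signal_counts <- function(table, alpha = attr(table, "alpha")) {
  emp <- lapply(seq_len(nrow(table)), function(i) {
    structure(list(d = table$emp_d[i], ci_low = table$emp_ci_low[i],
                   ci_high = table$emp_ci_high[i],
                   flags = if (table$emp_degenerate[i]) "degenerate" else
                     character()),
              class = "prop_comparison")
  })
  count_signals(fisher_p = table$fisher_p, empirical = emp,
                regression_p = table$mean_p,
                distributional_p = table$dist_p, alpha = alpha)
}

#' @export
print.signal_table <- function(x, ...) {
  al <- attr(x, "arm_levels")
  cat(sprintf("signal screen: %d outcome x tail tests (no multiplicity adjustment), alpha = %s\n",
              attr(x, "n_tests"), format(attr(x, "alpha"))))
  cat(sprintf("arms: control = %s, treatment = %s\n", al[1], al[2]))
  df <- data.frame(
    outcome = x$outcome, tail = x$tail,
    `control n/N` = sprintf("%d/%d (%.2f)", x$events_c, x$n_c, x$prop_c),
    `treatment n/N` = sprintf("%d/%d (%.2f)", x$events_t, x$n_t, x$prop_t),
    `mean diff [CI], p` = ifelse(is.na(x$mean_diff), "NE", sprintf(
      "%s, %s", format_est_ci(x$mean_diff, x$mean_ci_low, x$mean_ci_high),
      format_p(x$mean_p))),
    method = x$dist_method,
    `dist diff [DCI], p` = ifelse(is.na(x$dist_d), "NE", sprintf(
      "%s, %s", format_est_ci(x$dist_d, x$dist_ci_low, x$dist_ci_high),
      format_p(x$dist_p))),
    `Fisher p` = format_p(x$fisher_p),
    `emp diff [CI]` = paste0(
      format_est_ci(x$emp_d, x$emp_ci_low, x$emp_ci_high),
      ifelse(x$emp_degenerate, " (degenerate)", "")),
    check.names = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  sc <- signal_counts(x)
  cat("signals:", paste(sprintf("%s %d", names(sc), sc), collapse = ", "),
      "\n")
  tl <- attr(x, "method_tally")
  cat("method tally (per outcome):",
      paste(sprintf("%s %d", names(tl), tl), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.signal_table` <- function(x, ...) {
  # subsets are plain data.frames; the report attributes no longer apply
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}

#' Write a signal table to disk
#'
#' `format = "csv"` writes every column at full precision (re-reading the
#' file reproduces the values exactly); `format = "text"` writes the
#' human-readable report with proportions and differences at 2 decimal
#' places, p-values rendered `"< 0.01"` below 0.01, and non-estimable
#' entries as `NE`.
#'
#' @param table a `signal_table`.
#' @param path output path.
#' @param format `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(table, path, format = c("csv", "text")) {
  format <- match.arg(format)
  stopifnot(nrow(table) > 0)
  if (format == "csv") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                     na = "NE")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    sink(con)
    on.exit(sink(), add = TRUE, after = FALSE)
    print(table)
  }
  invisible(path)
}

#' Read back a CSV signal table
#'
#' @param path a CSV written by [write_signal_table()].
#' @return a data.frame with the full-precision columns.
#' @export
read_signal_table <- function(path) {
  utils::read.csv(path, na.strings = "NE", stringsAsFactors = FALSE)
}
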