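#' Read long-format trial laboratory data
#'
#' Reads a CSV of repeated laboratory/clinical measurements, one row per
#' participant x visit x outcome, and validates it as a two-arm trial
#' dataset. Required columns (after applying `dialect`) are `subject_id`,
#' `arm`, `visit_week`, `outcome` and `value`; any further columns are kept
#' as covariates. Non-numeric or blank values are recorded as missing and a
#' count is reported.
#'
#' @param path path to a CSV file with a header row, UTF-8, `.` decimal
#'   separator.
#' @param dialect optional named character vector mapping the required
#'   column names to the names used in the file, e.g.
#'   `c(subject_id = "USUBJID", value = "AVAL")`.
#' @param arm_levels optional length-2 character vector giving the arm
#'   labels in the order (control, treatment). Defaults to sorted order
#'   with a message.
#' @return a `trial_dataset`: a data.frame with the standard columns plus
#'   covariates, and attributes `arm_levels` (control first) and
#'   `covariates`.
#' @seealso [write_lab_data()], [select_endpoint_visit()]
#' @export
read_lab_data <- function(path, dialect = NULL, arm_levels = NULL) {
  if (!file.exists(path)) {
    stop("lab data file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c("subject_id", "arm", "visit_week", "outcome", "value")
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      idx <- match(dialect[[std]], names(df))
      if (!is.na(idx)) names(df)[idx] <- std
    }
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("configuration error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- df$value
  df$value <- suppressWarnings(as.numeric(raw))
  df$visit_week <- suppressWarnings(as.numeric(df$visit_week))
  n_missing <- sum(is.na(df$value) & nzchar(trimws(raw)) &
                     !toupper(trimws(raw)) %in% c("NA", ""))
  n_blank <- sum(is.na(df$value)) - n_missing
  message(sprintf("read %d records (%d non-numeric, %d blank/NA values set missing)",
                  nrow(df), n_missing, n_blank))
  covars <- setdiff(names(df), required)
  as_trial_dataset(df, arm_levels = arm_levels, covariates = covars)
}

#' Construct and validate a trial dataset
#'
#' Validates the two-arm trial invariants: every subject belongs to exactly
#' one arm, (subject, visit, outcome) triples are unique, and the arm column
#' takes exactly two values.
#'
#' @param df data.frame with columns `subject_id`, `arm`, `visit_week`,
#'   `outcome`, `value` and optional covariate columns.
#' @param arm_levels optional `c(control, treatment)` labels.
#' @param covariates character vector of covariate column names.
#' @return a validated `trial_dataset`.
#' @export
as_trial_dataset <- function(df, arm_levels = NULL, covariates = character()) {
  stopifnot(is.data.frame(df))
  required <- c("subject_id", "arm", "visit_week", "outcome", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("configuration error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  arms <- sort(unique(as.character(df$arm)))
  if (length(arms) != 2L) {
    stop("data error: expected exactly 2 arm labels, found ",
         length(arms), ": ", paste(arms, collapse = ", "), call. = FALSE)
  }
  if (is.null(arm_levels)) {
    arm_levels <- arms
  } else {
    if (!setequal(arm_levels, arms)) {
      stop("data error: arm_levels do not match the arm labels in the data",
           call. = FALSE)
    }
  }
  per_subj <- tapply(as.character(df$arm), df$subject_id,
                     function(a) length(unique(a)))
  if (any(per_subj > 1)) {
    bad <- names(per_subj)[per_subj > 1][1]
    stop("data error: subject ", bad, " appears in more than one arm",
         call. = FALSE)
  }
  key <- paste(df$subject_id, df$visit_week, df$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "data error: duplicate (subject, visit, outcome) triple: (%s, %s, %s)",
      d$subject_id, d$visit_week, d$outcome), call. = FALSE)
  }
  structure(df, class = c("trial_dataset", "data.frame"),
            arm_levels = arm_levels, covariates = covariates)
}

#' Write a trial dataset back to CSV
#'
#' Inverse of [read_lab_data()]: values round-trip exactly (full precision).
#'
#' @param dataset a `trial_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lab_data <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read reference ranges defining abnormality thresholds
#'
#' Reads a YAML mapping of outcome name to `low` / `high` thresholds (and an
#' optional `units` string). Values below `low` or above `high` are treated
#' as abnormal downstream; an outcome may have one or both thresholds.
#'
#' @param path path to a YAML file, e.g.
#'   `potassium: {low: 3.5, high: 5.5, units: mmol/L}`.
#' @return a list of `reference_range` objects (fields `outcome`, `low`,
#'   `high`, `units`), in file order.
#' @export
read_reference_ranges <- function(path) {
  if (!file.exists(path)) {
    stop("reference range file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("configuration error: no reference ranges in file",
                         call. = FALSE)
  lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    reference_range(nm, low = entry$low, high = entry$high,
                    units = entry$units)
  })
}

#' @rdname read_reference_ranges
#' @param outcome outcome name.
#' @param low,high abnormality thresholds in outcome units; at least one
#'   must be given and `low < high` when both are.
#' @param units optional units string.
#' @export
reference_range <- function(outcome, low = NULL, high = NULL, units = NULL) {
  if (is.null(low) && is.null(high)) {
    stop("configuration error: outcome '", outcome,
         "' has no thresholds", call. = FALSE)
  }
  if (!is.null(low) && !is.null(high) && low >= high) {
    stop("configuration error: outcome '", outcome,
         "' has low >= high (", low, " >= ", high, ")", call. = FALSE)
  }
  structure(list(outcome = outcome,
                 low = if (is.null(low)) NULL else as.numeric(low),
                 high = if (is.null(high)) NULL else as.numeric(high),
                 units = units),
            class = "reference_range")
}

#' Summarise one arm's values
#'
#' Sufficient statistics consumed by the distributional methods: sample
#' size, mean, SD (n - 1 denominator) and the moment coefficient of
#' skewness `b1 = m3 / m2^(3/2)` computed from central moments with `n`
#' denominators. The small-sample adjusted coefficient
#' `G1 = b1 * sqrt(n(n-1)) / (n-2)` is available via `adjust = TRUE`.
#'
#' @param values numeric vector; missing values dropped.
#' @param adjust use the small-sample adjusted skewness coefficient.
#' @return an `arm_summary`: list with `n`, `mean`, `sd`, `skewness` and
#'   `zero_variance`.
#' @examples
#' summarize_arm(c(1, 2, 3)) # mean 2, sd 1, skewness 0
#' @export
summarize_arm <- function(values, adjust = FALSE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    stop("insufficient data: need at least 2 non-missing values, got ", n,
         call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    return(arm_summary(n = n, mean = m, sd = 0, skewness = NA_real_))
  }
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  g <- m3 / m2^1.5
  if (adjust) g <- g * sqrt(n * (n - 1)) / (n - 2)
  arm_summary(n = n, mean = m, sd = s, skewness = g)
}

#' @rdname summarize_arm
#' @param n,mean,sd,skewness construct a summary directly from statistics
#'   (e.g. from a publication) rather than raw values.
#' @export
arm_summary <- function(n, mean, sd, skewness = 0) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 skewness = skewness, zero_variance = (sd == 0)),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("arm summary: n = %d, mean = %.4g, sd = %.4g, skewness = %.4g\n",
              x$n, x$mean, x$sd, x$skewness))
  invisible(x)
}

#' Select the endpoint visit cross-section
#'
#' Reduces a repeated-measures trial dataset to one value per subject and
#' outcome: either the last visit at which a non-missing value was observed
#' (`rule = "last"`, the default endpoint definition, so subjects missing
#' the final scheduled visit are not dropped) or a specific scheduled week
#' (`rule = week`, numeric).
#'
#' @param dataset a `trial_dataset`.
#' @param rule `"last"` or a numeric week.
#' @return a data.frame with one row per subject x outcome (columns as the
#'   input, `visit_week` giving the visit used), preserving covariates.
#' @export
select_endpoint_visit <- function(dataset, rule = "last") {
  stopifnot(nrow(dataset) > 0)
  df <- as.data.frame(dataset)
  if (identical(rule, "last")) {
    ok <- !is.na(df$value)
    sub <- df[ok, , drop = FALSE]
    key <- paste(sub$subject_id, sub$outcome, sep = "\r")
    ord <- order(key, sub$visit_week)
    sub <- sub[ord, , drop = FALSE]
    keep <- !duplicated(key[ord], fromLast = TRUE)
    out <- sub[keep, , drop = FALSE]
  } else {
    wk <- as.numeric(rule)
    out <- df[!is.na(df$visit_week) & df$visit_week == wk &
                !is.na(df$value), , drop = FALSE]
    present <- unique(df$outcome)
    got <- unique(out$outcome)
    absent <- setdiff(present, got)
    if (length(absent)) {
      stop("data error: week ", wk, " has no observed values for outcome(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  rownames(out) <- NULL
  attr(out, "arm_levels") <- attr(dataset, "arm_levels")
  attr(out, "covariates") <- attr(dataset, "covariates")
  out
}
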