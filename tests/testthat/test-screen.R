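make_screen_fixture <- function(seed = 100, shift = 0) {
  sc <- trial_scenario(
    n_t = 80, n_c = 80,
    outcomes = list(
      scenario_outcome("alb", "normal", mean = 40, sd = 4,
                       shift = shift * 4, low = 32, high = 48),
      scenario_outcome("crp", "skew_normal", mean = 5, sd = 2,
                       skewness = 0.5, low = 1)),
    covariates = list(binary = list(name = "strat", prevalence = 0.5,
                                    effect = 0.3)),
    visits = c(0, 12, 24), missing_rate = 0.02, seed = seed)
  generate_trial(sc)
}

test_that("a null screen yields the expected shape and rare signals", {
  ds <- make_screen_fixture(seed = 100)
  rg <- list(reference_range("alb", low = 32, high = 48),
             reference_range("crp", low = 1))
  st <- suppressWarnings(run_screen(ds, rg, covariates = "strat"))
  expect_s3_class(st, "signal_table")
  # alb has both tails, crp only the low tail
  expect_equal(nrow(st), 3L)
  expect_equal(st$outcome, c("alb", "alb", "crp"))
  expect_equal(st$tail, c("below", "above", "below"))
  expect_false(any(st$signal_distributional & st$signal_regression &
                     st$signal_fisher))
  # distributional p equals the adjusted-model p row by row where adjusted
  adj <- grepl("^adjusted", st$dist_method)
  expect_equal(st$dist_p[adj], st$mean_p[adj], tolerance = 1e-12)
})

test_that("a half-SD shift is flagged by regression and distributional", {
  ds <- make_screen_fixture(seed = 101, shift = -0.5)
  rg <- list(reference_range("alb", low = 32),
             reference_range("crp", low = 1))
  st <- suppressWarnings(run_screen(ds, rg, covariates = "strat"))
  row <- st[st$outcome == "alb", ]
  expect_true(row$signal_distributional)
  expect_lt(row$mean_p, 0.05)
  expect_lt(row$dist_p, 0.05)
  # the table's summary equals count_signals on its rows
  sc <- signal_counts(st)
  expect_equal(unname(sc["distributional"]),
               sum(st$signal_distributional))
  expect_equal(unname(sc["fisher"]), sum(st$signal_fisher))
})

test_that("rows are ordered alphabetically by outcome", {
  sc <- trial_scenario(40, 40, list(
    scenario_outcome("zeta", mean = 0, sd = 1, low = -2),
    scenario_outcome("alpha", mean = 0, sd = 1, low = -2)), seed = 7)
  ds <- generate_trial(sc)
  st <- suppressWarnings(run_screen(ds, list(
    reference_range("zeta", low = -2), reference_range("alpha", low = -2))))
  expect_equal(st$outcome, c("alpha", "zeta"))
})

test_that("missing configured outcomes are a configuration error", {
  ds <- make_screen_fixture()
  expect_error(suppressWarnings(
    run_screen(ds, list(reference_range("nope", low = 0)))),
    "configuration error")
})

test_that("screen output round-trips through CSV at full precision", {
  ds <- make_screen_fixture(seed = 102)
  rg <- list(reference_range("alb", low = 32, high = 48),
             reference_range("crp", low = 1))
  st <- suppressWarnings(run_screen(ds, rg, covariates = "strat"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(st, path, "csv")
  back <- read_signal_table(path)
  for (col in c("dist_d", "dist_ci_low", "dist_ci_high", "dist_p",
                "emp_d", "mean_diff", "fisher_p")) {
    expect_equal(back[[col]], st[[col]], tolerance = 1e-12)
  }
  # identical runs give byte-identical CSVs
  st2 <- suppressWarnings(run_screen(ds, rg, covariates = "strat"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(st2, path2, "csv")
  expect_identical(readLines(path), readLines(path2))
})

test_that("text report renders p-values and degenerate rows per convention", {
  ds <- make_screen_fixture(seed = 103, shift = -1)
  # thresholds far in the tail give zero events in both arms for crp
  rg <- list(reference_range("alb", low = 32),
             reference_range("crp", low = -50))
  st <- suppressWarnings(run_screen(ds, rg, covariates = "strat"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_signal_table(st, path, "text")
  txt <- readLines(path)
  expect_true(any(grepl("< 0.01", txt)))       # strong shift on alb
  expect_true(any(grepl("NE", txt)))           # zero-event Fisher
  expect_true(any(grepl("0.00 \\[0.00, 0.00\\] \\(degenerate\\)", txt)))
  expect_true(any(grepl("no multiplicity adjustment", txt)))
})

test_that("zero-variance outcomes keep empirical columns, flag distributional", {
  df <- data.frame(
    subject_id = sprintf("s%02d", 1:40),
    arm = rep(c("c", "t"), 20),
    visit_week = 24,
    outcome = "flat",
    value = rep(5, 40))
  ds <- as_trial_dataset(df)
  expect_warning(st <- run_screen(ds, list(reference_range("flat", low = 4))),
                 "zero variance")
  expect_equal(st$dist_method, "NE")
  expect_true(is.na(st$dist_d))
  expect_equal(st$events_t, 0L)
  expect_true(st$emp_degenerate)
})

test_that("the formula front-end agrees with the module functions", {
  set.seed(55)
  df <- data.frame(arm = rep(c("placebo", "active"), each = 100),
                   value = rnorm(200, rep(c(0, 0.3), each = 100)),
                   x = rnorm(200))
  fit <- distdiff(value ~ arm, df, threshold = -1.645, tail = "below",
                  arm_levels = c("placebo", "active"))
  ref <- diff_auto(summarize_arm(df$value[df$arm == "active"]),
                   summarize_arm(df$value[df$arm == "placebo"]),
                   -1.645, "below")
  expect_equal(coef(fit), c(difference = ref$d))
  expect_equal(unname(confint(fit)[1, ]), c(ref$ci_low, ref$ci_high))
  # adjusted pathway
  fit_adj <- distdiff(value ~ arm + x, df, threshold = -1.645,
                      arm_levels = c("placebo", "active"))
  mod <- fit_adjusted_model(data.frame(value = df$value, arm = df$arm,
                                       x = df$x),
                            covariates = "x",
                            arm_levels = c("placebo", "active"))
  refa <- adjusted_distributional_difference(mod, -1.645, "below")
  expect_equal(unname(coef(fit_adj)), refa$d)
  expect_equal(fit_adj$comparison$p_value, refa$p_value)
  # empirical comparator
  fit_emp <- distdiff(value ~ arm, df, threshold = -1.645,
                      method = "empirical",
                      arm_levels = c("placebo", "active"))
  expect_equal(fit_emp$comparison$method, "empirical")
  expect_output(print(fit), "distributional difference")
  expect_output(summary(fit), "method choice")
})
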