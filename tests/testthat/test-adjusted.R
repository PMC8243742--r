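test_that("without covariates the model reproduces raw arm statistics", {
  set.seed(8)
  df <- data.frame(value = rnorm(90), arm = rep(c("c", "t"), c(40, 50)))
  fit <- fit_adjusted_model(df, arm_levels = c("c", "t"))
  expect_equal(unname(fit$marginal_means["c"]),
               mean(df$value[df$arm == "c"]), tolerance = 1e-12)
  expect_equal(unname(fit$marginal_means["t"]),
               mean(df$value[df$arm == "t"]), tolerance = 1e-12)
  sp <- sqrt(
    (39 * var(df$value[df$arm == "c"]) + 49 * var(df$value[df$arm == "t"]))
    / 88)
  expect_equal(fit$resid_sd, sp, tolerance = 1e-12)
  expect_equal(fit$random_intercept_var, 0)
  expect_equal(unname(fit$n_per_arm), c(40L, 50L))
})

test_that("the linear model recovers a known treatment effect", {
  set.seed(9)
  n <- 2000
  a <- rep(0:1, each = n / 2)
  x <- rnorm(n)
  df <- data.frame(value = 1 + 0.5 * a + 2 * x + rnorm(n),
                   arm = ifelse(a == 1, "t", "c"), x = x)
  fit <- fit_adjusted_model(df, covariates = "x", arm_levels = c("c", "t"))
  est <- fit$marginal_means["t"] - fit$marginal_means["c"]
  expect_lt(abs(est - 0.5), 3 * fit$coef_se)
  expect_equal(unname(est), fit$coef, tolerance = 1e-10)
  expect_equal(fit$resid_sd, 1, tolerance = 0.1)
})

test_that("constant covariates are dropped and collinearity is an error", {
  set.seed(10)
  df <- data.frame(value = rnorm(40), arm = rep(c("c", "t"), 20),
                   z = 1, x = rnorm(40))
  expect_warning(fit <- fit_adjusted_model(df, covariates = c("z", "x"),
                                           arm_levels = c("c", "t")),
                 "constant covariate")
  expect_equal(fit$covariates, "x")
  df$x2 <- 2 * df$x
  expect_error(
    suppressWarnings(fit_adjusted_model(df, covariates = c("x", "x2"),
                                        arm_levels = c("c", "t"))),
    "collinear")
})

test_that("random-intercept fits converge to the linear model as variance -> 0", {
  set.seed(12)
  n <- 400
  df <- data.frame(value = rnorm(n) + rep(c(0, 0.3), each = n / 2),
                   arm = rep(c("c", "t"), each = n / 2),
                   site = sample(letters[1:8], n, replace = TRUE))
  fit_ri <- suppressMessages(fit_adjusted_model(
    df, random_intercept = "site", arm_levels = c("c", "t")))
  fit_lm <- fit_adjusted_model(df, arm_levels = c("c", "t"))
  expect_lt(fit_ri$random_intercept_var, 0.05)
  a_ri <- adjusted_distributional_difference(fit_ri, -1.2, "below")
  a_lm <- adjusted_distributional_difference(fit_lm, -1.2, "below")
  expect_lt(abs(a_ri$d - a_lm$d), 0.01)
})

test_that("with no covariates the adjusted difference equals the unadjusted", {
  set.seed(13)
  df <- data.frame(value = rnorm(160), arm = rep(c("c", "t"), 80))
  fit <- fit_adjusted_model(df, arm_levels = c("c", "t"))
  adj <- adjusted_distributional_difference(fit, -1, "below")
  un <- diff_equal_variance(summarize_arm(df$value[df$arm == "t"]),
                            summarize_arm(df$value[df$arm == "c"]),
                            -1, "below")
  expect_equal(adj$d, un$d, tolerance = 1e-10)
  expect_equal(adj$se, un$se, tolerance = 1e-10)
  # reported p is the model's treatment-coefficient p
  expect_equal(adj$p_value, fit$coef_p, tolerance = 1e-12)
  expect_equal(adj$details$delta_p,
               2 * pnorm(-abs(adj$d / adj$se)), tolerance = 1e-12)
})

test_that("a balanced prognostic covariate makes adjustment more precise", {
  set.seed(14)
  wins <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    n <- 120
    strat <- rep(rep(0:1, each = n / 4), 2)   # balanced within arms
    a <- rep(0:1, each = n / 2)
    y <- 0.2 * a + 1.5 * strat + rnorm(n)
    df <- data.frame(value = y, arm = ifelse(a == 1, "t", "c"), x = strat)
    fit_adj <- fit_adjusted_model(df, covariates = "x",
                                  arm_levels = c("c", "t"))
    fit_un <- fit_adjusted_model(df, arm_levels = c("c", "t"))
    x0 <- quantile(y, 0.1)
    se_adj <- adjusted_distributional_difference(fit_adj, x0, "below")$se
    se_un <- adjusted_distributional_difference(fit_un, x0, "below")$se
    wins <- wins + (se_adj <= se_un)
  }
  expect_gte(wins / reps, 0.9)
})

test_that("distributional precision tracks the regression coefficient", {
  # |d|/se(d) within 10% of |beta|/se(beta) for small effects
  set.seed(15)
  for (r in 1:10) {
    n <- 600
    a <- rep(0:1, each = n / 2)
    x <- rnorm(n)
    df <- data.frame(value = 0.15 * a + x * 0.5 + rnorm(n),
                     arm = ifelse(a == 1, "t", "c"), x = x)
    fit <- fit_adjusted_model(df, covariates = "x",
                              arm_levels = c("c", "t"))
    x0 <- quantile(df$value, 0.2)
    adj <- adjusted_distributional_difference(fit, x0, "below")
    z_dist <- abs(adj$d / adj$se)
    z_coef <- abs(fit$coef / fit$coef_se)
    expect_lt(abs(z_dist - z_coef) / z_coef, 0.1)
  }
})

test_that("skew-normal residual family responds to skewed residuals", {
  set.seed(16)
  n <- 1000
  e <- rlnorm(n, sdlog = 0.6)
  e <- (e - mean(e)) / sd(e)
  df <- data.frame(value = rep(c(0, 0.3), each = n / 2) + e,
                   arm = rep(c("c", "t"), each = n / 2))
  fit <- fit_adjusted_model(df, arm_levels = c("c", "t"))
  sk <- adjusted_distributional_difference(fit, -1.0, "below",
                                           residual_family = "skew_normal")
  no <- adjusted_distributional_difference(fit, -1.0, "below")
  expect_false(isTRUE(all.equal(sk$d, no$d)))
  expect_gt(sk$se, 0)
  # a clamped residual skewness is surfaced
  e2 <- rlnorm(n, sdlog = 1.2)
  df2 <- data.frame(value = rep(c(0, 0.3), each = n / 2) + e2,
                    arm = rep(c("c", "t"), each = n / 2))
  fit2 <- fit_adjusted_model(df2, arm_levels = c("c", "t"))
  sk2 <- adjusted_distributional_difference(fit2, 0.2, "below",
                                            residual_family = "skew_normal")
  expect_true("skewness_clamped" %in% sk2$flags)
})
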