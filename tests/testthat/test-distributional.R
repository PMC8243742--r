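test_that("normal proportion matches closed-form evaluation", {
  e <- normal_proportion(arm_summary(100, 0, 1), 0, "below")
  expect_equal(e$p, 0.5)
  expect_equal(e$se, dnorm(0) / 10, tolerance = 1e-12)
  # mean 1, s 2, n 50, x0 = 0: p = Phi(-0.5), se = (2/sqrt(50)) * phi(0.5)/2
  e2 <- normal_proportion(arm_summary(50, 1, 2), 0, "below")
  expect_equal(e2$p, pnorm(-0.5), tolerance = 1e-12)
  expect_equal(e2$se, (2 / sqrt(50)) * dnorm(0.5) / 2, tolerance = 1e-12)
  expect_equal(e2$se, 0.0497896, tolerance = 1e-6)
  expect_error(normal_proportion(arm_summary(10, 1, 0), 0), "degenerate")
})

test_that("below and above tails are complementary with identical se", {
  for (m in c(-1, 0.5)) {
    for (x0 in c(-1.645, 0, 2)) {
      s <- arm_summary(80, m, 1.3)
      lo <- normal_proportion(s, x0, "below")
      hi <- normal_proportion(s, x0, "above")
      expect_equal(lo$p + hi$p, 1, tolerance = 1e-12)
      expect_equal(lo$se, hi$se)
    }
  }
})

test_that("equal-variance difference matches the closed-form oracle", {
  t <- arm_summary(200, 0.3, 1)
  c0 <- arm_summary(200, 0, 1)
  cmp <- diff_equal_variance(t, c0, -1.645, "below")
  expect_equal(cmp$d, pnorm(-1.945) - pnorm(-1.645), tolerance = 1e-12)
  expect_equal(round(cmp$d, 5), -0.0241)
  se_oracle <- sqrt(dnorm(-1.645, 0.3, 1)^2 / 200 +
                      dnorm(-1.645, 0, 1)^2 / 200)
  expect_equal(cmp$se, se_oracle, tolerance = 1e-12)
  # null identity
  null <- diff_equal_variance(c0, c0, -1.645, "below")
  expect_equal(null$d, 0)
  expect_equal(null$p_value, 1)
})

test_that("unequal-variance formula matches hand evaluation and R = 1 limit", {
  t <- arm_summary(100, 1, 2)
  c0 <- arm_summary(100, 0, 1)
  cmp <- diff_unequal_variance(t, c0, -1.645, "below")
  # R estimated = 4; s_uneq = sqrt((99*4 + 99*4*1)/198) = 2
  expect_equal(cmp$details$R, 4)
  expect_equal(cmp$details$s_uneq, 2, tolerance = 1e-12)
  expect_true("R_estimated" %in% cmp$flags)
  d_oracle <- pnorm((-1.645 - 1) / 2) - pnorm(-1.645 / 1)
  se_oracle <- sqrt(4 / 100 * dnorm(-1.645, 1, 2)^2 +
                      1 / 100 * dnorm(-1.645, 0, 1)^2)
  expect_equal(cmp$d, d_oracle, tolerance = 1e-12)
  expect_equal(cmp$se, se_oracle, tolerance = 1e-12)
  # R = 1 collapses exactly onto the equal-variance method
  eq <- diff_equal_variance(t, c0, -1.645, "below")
  u1 <- diff_unequal_variance(t, c0, -1.645, "below", R = 1)
  expect_equal(u1$d, eq$d, tolerance = 1e-12)
  expect_equal(u1$se, eq$se, tolerance = 1e-12)
  expect_error(diff_unequal_variance(t, c0, -1.645, "below", R = -2),
               "positive")
})

test_that("large-effect correction is an exact se multiplier", {
  t <- arm_summary(100, 1, 2)
  c0 <- arm_summary(100, 0, 1)
  plain <- diff_unequal_variance(t, c0, -1.645, "below")
  corr <- diff_unequal_variance(t, c0, -1.645, "below", correction = 1.25,
                                large_effect = TRUE)
  expect_equal(corr$se, 1.25 * plain$se, tolerance = 1e-12)
  expect_true(all(c("correction_applied", "large_effect") %in% corr$flags))
  expect_false("correction_applied" %in% plain$flags)
})

test_that("skew-normal proportions agree with quadrature and normal limit", {
  p <- sn_from_moments(0, 1, 0)
  sn <- skew_normal_proportion(p, 100, 1, -0.5, "below")
  no <- normal_proportion(arm_summary(100, 0, 1), -0.5, "below")
  expect_equal(sn$p, no$p, tolerance = 1e-10)
  expect_equal(sn$se, no$se, tolerance = 1e-10)
  pars <- list(xi = 0, omega = 1, alpha = 3)
  est <- skew_normal_proportion(
    structure(pars, class = "sn_params"), 50, 1, 0, "below")
  expect_equal(est$p, psn_quadrature(0, 0, 1, 3), tolerance = 1e-8)
  est_hi <- skew_normal_proportion(
    structure(pars, class = "sn_params"), 50, 1, 0, "above")
  expect_equal(est$p + est_hi$p, 1, tolerance = 1e-12)
})

test_that("skew-normal difference reduces to the normal method at zero skew", {
  t <- arm_summary(150, 0.4, 1.2, skewness = 0)
  c0 <- arm_summary(120, 0, 1.2, skewness = 0)
  sk <- diff_skew_normal(t, c0, -1.5, "below")
  eq <- diff_equal_variance(t, c0, -1.5, "below")
  expect_equal(sk$d, eq$d, tolerance = 1e-6)
  expect_equal(sk$se, eq$se, tolerance = 1e-6)
})

test_that("small skewness leaves the difference close to the normal method", {
  t <- arm_summary(1000, 0.3, 1, skewness = 0.2)
  c0 <- arm_summary(1000, 0, 1, skewness = 0.2)
  sk <- diff_skew_normal(t, c0, -1.645, "below")
  eq <- diff_equal_variance(t, c0, -1.645, "below")
  expect_lt(abs(sk$d - eq$d), 0.01)
})

test_that("clamping propagates into difference flags", {
  t <- arm_summary(60, 0, 1, skewness = 1.4)
  c0 <- arm_summary(60, 0, 1, skewness = 0.2)
  cmp <- diff_skew_normal(t, c0, -1, "below")
  expect_true("skewness_clamped" %in% cmp$flags)
})

test_that("tail antisymmetry holds for every method", {
  t <- arm_summary(90, 0.5, 1.4, skewness = 0.6)
  c0 <- arm_summary(110, 0, 1, skewness = 0.3)
  for (f in list(diff_equal_variance, diff_unequal_variance,
                 diff_skew_normal)) {
    lo <- f(t, c0, -1, "below")
    hi <- f(t, c0, -1, "above")
    expect_equal(lo$d, -hi$d, tolerance = 1e-12)
    expect_equal(lo$se, hi$se, tolerance = 1e-12)
  }
})

test_that("below-threshold proportion decreases as the treatment mean rises", {
  p_prev <- Inf
  for (m in seq(-0.5, 1.5, by = 0.25)) {
    p <- normal_proportion(arm_summary(100, m, 1), -1, "below")$p
    expect_lt(p, p_prev)
    p_prev <- p
  }
})

test_that("distributional methods stay estimable with zero observed events", {
  # both arms entirely above the threshold: empirical events are zero
  set.seed(5)
  yt <- rnorm(60, 5, 0.5)
  yc <- rnorm(60, 5.2, 0.5)
  x0 <- 2
  counts <- dichotomise(yt, yc, x0, "below")
  expect_equal(counts$events_t + counts$events_c, 0L)
  for (f in list(diff_equal_variance, diff_unequal_variance,
                 diff_skew_normal)) {
    cmp <- f(summarize_arm(yt), summarize_arm(yc), x0, "below")
    expect_gt(cmp$se, 0)
    expect_true(is.finite(cmp$p_value))
  }
})

test_that("Wald interval and p behave per the normal reference", {
  w <- wald_interval_and_p(0, 0.1, 0.95)
  expect_equal(w$ci_low, -0.195996, tolerance = 1e-5)
  expect_equal(w$p_value, 1)
  w2 <- wald_interval_and_p(0.06, 0.0153, 0.95)
  expect_lt(w2$p_value, 0.01)
  expect_equal(w2$p_value, 2 * pnorm(-0.06 / 0.0153), tolerance = 1e-12)
  # width identity at 95%
  w3 <- wald_interval_and_p(0.3, 0.04, 0.95)
  expect_equal(w3$ci_high - w3$ci_low, 2 * 1.959964 * 0.04, tolerance = 1e-6)
  expect_error(wald_interval_and_p(0.2, 0), "degenerate")
  expect_true(wald_interval_and_p(0, 0)$degenerate)
})

test_that("zero-variance arms refuse distributional analysis", {
  z <- summarize_arm(c(5, 5, 5))
  ok <- arm_summary(50, 5, 1)
  expect_error(diff_equal_variance(z, ok, 4, "below"), "zero variance")
  expect_error(diff_skew_normal(ok, z, 4, "below"), "zero variance")
  expect_error(fit_skew_normal(z), "zero variance")
})
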