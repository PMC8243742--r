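# Independent oracles used across the suite.

# Skew-normal CDF by direct quadrature of the density formula (does not go
# through psn()/owen_t()).
psn_quadrature <- function(x, xi, omega, alpha) {
  dens <- function(t) {
    z <- (t - xi) / omega
    2 / omega * dnorm(z) * pnorm(alpha * z)
  }
  stats::integrate(dens, -Inf, x, rel.tol = 1e-10)$value
}

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, point probabilities from factorials via choose().
fisher_enumeration <- function(events_t, n_t, events_c, n_c) {
  m1 <- events_t + events_c
  n <- n_t + n_c
  xs <- max(0, m1 - n_c):min(m1, n_t)
  pr <- choose(m1, xs) * choose(n - m1, n_t - xs) / choose(n, n_t)
  p_obs <- pr[xs == events_t]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# A small two-outcome dataset used by several I/O tests.
make_tiny_dataset <- function() {
  as_trial_dataset(data.frame(
    subject_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    arm = rep(c("placebo", "placebo", "active", "active"), each = 2),
    visit_week = 24,
    outcome = rep(c("potassium", "sodium"), 4),
    value = c(4.1, 140, 3.4, 138, 4.5, 141, 3.9, 136),
    stringsAsFactors = FALSE))
}

# Monte-Carlo SE calibration harness: mean reported se over sd of estimates.
se_calibration <- function(gen_t, gen_c, x0, reps, compare, seed = 1) {
  set.seed(seed)
  d <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    cmp <- compare(gen_t(), gen_c(), x0)
    d[r] <- cmp$d
    se[r] <- cmp$se
  }
  list(ratio = mean(se) / sd(d), mean_d = mean(d), sd_d = sd(d))
}
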