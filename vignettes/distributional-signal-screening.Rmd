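---
title: "Distributional screening of continuous safety outcomes: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional screening of continuous safety outcomes: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesignal)
```

## The estimation problem

Safety screening in a two-arm randomised trial monitors many continuous
outcomes (blood counts, electrolytes, enzymes) against reference ranges.
The conventional analysis dichotomises each outcome at its range limits
and compares abnormal-value proportions between arms; with thresholds in
the tails of the distribution nearly all the information in the
continuous measurements is discarded, and the comparisons are badly
underpowered precisely where adverse drug reactions would first show.

The distributional approach estimates the same clinically interpretable
quantity — the difference in the proportions beyond a threshold — from
fitted distribution parameters instead of observed event counts. If an
arm's outcome is modelled as a distribution with location estimated by
the sample mean, the proportion below a threshold $x_0$ is the fitted
distribution function at $x_0$, and a first-order (delta-method)
expansion in the location gives

$$\operatorname{se}\{\hat p(x_0)\} \approx \frac{s}{\sqrt n}\, f(x_0),$$

with $f$ the fitted density. The between-arm difference $d = p_t - p_c$
combines the two arms' terms in quadrature. The resulting $z$-statistic
$d/\operatorname{se}(d)$ agrees with the two-sample comparison of means
to first order — the proportion comparison *retains the precision of the
comparison of means* (the package's acceptance suite verifies agreement
within 5% for standardised shifts up to 0.3 at 200+ per arm) — and the
estimate exists even when no abnormal values were observed at all.

## The three methods and when each applies

**Normal, equal variances** (`diff_equal_variance()`): both arms normal
with common variance; the pooled SD enters both arms' proportions and
standard errors. Because the pooled SD is shared, its estimation error
largely cancels in $d$, which is why the reported standard error is
almost exactly calibrated (Monte-Carlo ratio of mean reported se to the
empirical SD of $d$: 1.00 at 200 per arm).

**Normal, unequal variances** (`diff_unequal_variance()`): treatment may
inflate variability. The variance ratio $R = \sigma_t^2/\sigma_c^2$
rescales the pooled estimate,
$s_{uneq} = \sqrt{\{(n_t-1)s_t^2 + (n_c-1)R\,s_c^2\}/(n_t+n_c-2)}$, with
the treatment arm using $s_{uneq}$ and the control arm $s_{uneq}/\sqrt R$.
$R$ should ideally come from earlier studies of the same outcome; the
function accepts a known `R` and is then well calibrated (ratio 1.00 in
our simulations). When `R` is estimated from the observed SDs — the only
option in a blind screen — the standard error *underestimates* the true
sampling variability (we measure ratios of 0.70–0.78 at 100 per arm with
a fourfold ratio), which is why a `correction` multiplier is provided for
large effects. Its value is deliberately not defaulted above 1: validated
magnitudes depend on the design and should be taken from the simulation
literature on this estimator, or calibrated with
`simulate_operating_characteristics()` for the design at hand.

**Skew-normal** (`diff_skew_normal()`): for outcomes whose skewness makes
the normal model untenable, a three-parameter skew-normal (location
$\xi$, scale $\omega$, shape $\alpha$) is fitted to each arm by the
method of moments. The family's population skewness is bounded by about
$\pm 0.9953$, so sample skewness is clamped to $\pm 0.99$ before
inversion (flagged `skewness_clamped`); this matters because the
automated procedure routes every outcome with $|$skewness$| \ge 1$ here.
The distribution function is evaluated exactly as
$\Phi(z) - 2\,T(z, \alpha)$ with Owen's $T$ computed by adaptive
quadrature of its defining integral (arguments reduced to $|a| \le 1$ via
the standard identity; checked in the tests against closed forms and
against direct quadrature of the density to $10^{-8}$). The delta-method
standard error perturbs the location only, treating scale and shape as
fixed. Consequently it is calibrated when the shape is effectively known
(ratio 0.91–0.98 in our simulations at 500 per arm) but — like the
estimated-$R$ case above — understates the variability contributed by
estimating the shape from the same data (ratios down to 0.6 with
thresholds in the tail). Users screening strongly skewed outcomes should
read skew-normal standard errors as lower bounds; a resampling check with
the simulation harness is the honest sensitivity analysis, and no
skewed-plus-unequal-variance method is offered because none exists with
a validated standard error.

## The automated procedure

`select_method()` implements the screening-scale decision rule: the
skew-normal method when the skewness statistic is $\le -1$ or $\ge 1$;
otherwise a two-sided variance-ratio $F$ test (raw arm values,
doubled-smaller-tail convention) at $\alpha = 0.05$ chooses between the
unequal- and equal-variance normal methods, with the boundary
$p = \alpha$ kept on the equal-variance side — when uncertain, equal
variance is the safer assumption. A standardised effect size (Glass's
$\Delta$, control-arm SD in the denominator) above 0.75 flags a large
effect, the regime in which the estimated-$R$ correction applies. All
three cutoffs are arguments with these defaults.

Two readings of "the outcome's skewness" are defensible and both are
provided: the per-arm skewness largest in absolute value (default —
treatment can induce skewness in one arm only) or the skewness of pooled
mean-centred residuals (`skewness_basis = "pooled_residual"` in
`run_screen()`), which is less noisy but can mask one-arm skewness.

The procedure is itself a battery of tests, so running it across many
outcomes over-identifies the skew-normal and unequal-variance branches
and inflates the screen's overall type-I error: in our null simulations
(100 per arm, 5th-percentile threshold, 10,000 replicates) the fixed
equal-variance test rejects at 0.040 while the selector-driven test
rejects at 0.075, the excess coming almost entirely from replicates where
a significant $F$ test selected an extreme estimated $R$. The screen
therefore reports a per-run tally of selections, and its outputs are
labelled signals to be confirmed, never adjusted significance claims.

## Covariate adjustment

Adjusting for randomisation stratification variables is standard trial
practice and sharpens the treatment-effect estimate.
`fit_adjusted_model()` fits $Y = \beta_0 + \beta_A A + \beta X + \epsilon$
by least squares (or adds a random intercept, fitted by REML via lme4,
for clustered designs), and `adjusted_distributional_difference()` turns
the fit into proportions: each arm's marginal mean $E(Y \mid A=a, X)$ —
evaluated at the sample means of the covariates, categorical covariates
at their observed proportions — is the location, and the total SD
$\sqrt{\sigma_e^2 + \sigma_a^2}$ the scale, of the residual distribution
whose CDF is evaluated at the threshold. The residual family is normal
or, when the selector demands it, a skew-normal fitted to the model
residuals. Two numerical conventions are worth stating explicitly: the
CDF argument is $(x_0 - E)/\mathrm{sd}$, oriented so a larger mean gives
a smaller below-threshold proportion, and the divisor is the SD, not the
variance — the only reading consistent with the delta-method density
form of the standard error. With no covariates and no random intercept
the whole construction collapses exactly (to $10^{-10}$ in the tests)
onto the unadjusted equal-variance method.

The reported p-value for an adjusted distributional difference is the
treatment coefficient's p-value from the model: the precision of the
adjusted proportion difference reflects the precision of that
coefficient (the tests check $|d|/\operatorname{se}(d)$ tracks
$|\beta_A|/\operatorname{se}(\beta_A)$ within 10% for small effects).
The delta-method z-test p-value is kept in `details$delta_p`. When the
selector chooses unequal variances the adjusted machinery does not apply
(adjustment composes only with normal or skew-normal residuals); the
screen then reports the unadjusted unequal-variance estimate and says so
in a warning.

## Empirical comparators and conventions

The screen always reports what standard practice would have reported.
Dichotomisation uses strict inequalities — a value equal to a
reference-range limit is normal, since the ranges are inclusive normal
intervals (`strict = FALSE` flips this; the original convention is not
recoverable from published tables). Fisher's exact test uses the
minimum-likelihood two-sided convention by default, with the
doubled-tail convention selectable: on one published potassium table
(0/66 vs 4/61) the two give 0.050 and 0.069 against a published 0.06, so
the original software's convention is genuinely ambiguous and we
document rather than resolve it. Fisher returns `NE` (non-estimable)
exactly when both arms have zero events. The Wald difference-in-
proportions interval is unpooled with no continuity correction — the
variant that reproduces published haemoglobin and lymphocyte intervals
at 2 decimal places — and a both-arms-zero table yields the notorious
`0.00 [0.00, 0.00]`, which is reported but flagged `degenerate` and
never counted as a signal; the distributional estimate for the same data
has positive standard error.

## The synthetic-trial generator

`generate_trial()` exists so every pipeline component is testable
without access to restricted subject-level trial data. A scenario fixes
arm sizes, per-outcome families (normal; skew-normal through the same
moment map as the fitting code, making recovery tests self-consistent;
shifted/reflected lognormal for $|$skewness$| \ge 1$), a treatment mean
shift applied from the first post-baseline visit, a variance ratio, one
categorical and one binary covariate whose effects (in control-SD units)
enter as time-constant subject effects, a visit schedule, and
missing-completely-at-random dropout. Draws use one RNG substream per
outcome (hashed from the master seed) so adding an outcome never
perturbs existing ones; within a substream replicates are drawn
sequentially. We initially derived a fresh substream per replicate and
found measurably correlated variance ratios across nearby seeds — a
cautionary tale worth recording: null $F$-test rejection at 0.079
instead of 0.046.

The preset `scenario_sirius_like()` mirrors the shape of a small severe
eosinophilic asthma trial: 61 vs 66 participants, ten blood outcomes
with low-tail thresholds spanning null event rates from 0 to a few
percent, a strong eosinophil-depleting treatment effect (event rate
above 40%), stratification by country and prior oral corticosteroid
duration, six visits over 24 weeks, 3% missingness. Where the emulated
population's parameters are not published we chose representative
laboratory means and SDs once; they are illustrative, not calibrated to
any dataset.

What the generator does *not* emulate — and hence what green tests do
not establish about real data: informative missingness, within-subject
correlation over visits (post-baseline draws are independent),
measurement rounding, assay floor effects, and distributions outside the
three families. Real screens should treat the operating characteristics
as design-stage guidance, not guarantees.

## Numerical and design choices, in brief

* Skewness statistic: moment coefficient $m_3/m_2^{3/2}$ ($n$
  denominators), matching mainstream statistical software; the
  small-sample $G_1$ adjustment is available via `adjust = TRUE`.
* Equal-variance standard error uses per-arm $n_t, n_c$; with equal arms
  this is the single-$n$ textbook form, and unequal arms are handled
  consistently with the unequal-variance formula.
* Endpoint rule `"last"` means the last *observed* value per subject and
  outcome, so missing final visits do not drop subjects; analyses are
  complete-case within outcome and tail, with dropped counts logged.
* Zero-variance arms refuse distributional analysis with an explicit
  error (the screen marks such rows `NE`) rather than returning a
  boundary proportion of 0 or 1.
* Degenerate comparisons ($\operatorname{se} = 0$) report $p = 1$ when
  $d = 0$ and are flagged; an all-events-versus-no-events empirical
  table keeps its estimate but is flagged and excluded from signal
  counts.
* Owen's $T$ quadrature tolerances are $10^{-12}$ relative; skew-normal
  CDF values agree with independent quadrature to $10^{-8}$.
* No multiplicity adjustment anywhere, by design; the report header
  states the number of tests performed.

## Problem sizes used in the test and acceptance suites

Monte-Carlo checks use 2,000 replicates for standard-error calibration
(5% tolerance for the normal method, 10% for the others on their home
ground), 10,000 null replicates for the type-I error of the fixed
equal-variance test (accepted in [0.04, 0.06]) and its selector-driven
inflation, 5,000 replicates for the power comparison against Fisher's
exact test at 60 per arm and a 0.5 SD shift, and 1,000 replicates per
generating family for selector recovery (accepted at $\ge$ 90% with 500
per arm). These sizes keep Monte-Carlo error comfortably inside each
tolerance while the full suite runs in about a minute and a half.
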