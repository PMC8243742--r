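Package: aesignal
Title: Distributional Signal Detection for Continuous Adverse Event
    Outcomes in Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens continuous laboratory and clinical safety outcomes in
    two-arm randomised controlled trials for adverse drug reaction signals.
    Between-arm differences in the proportions of participants with
    abnormally low or high values are estimated from fitted distribution
    parameters (normal with equal or unequal variances, or skew-normal)
    rather than from observed event counts, so the comparison of
    proportions retains the precision of a comparison of means. Includes
    an automated procedure that selects the distributional method from the
    observed skewness and a variance-ratio test, covariate-adjusted
    estimates via marginal means from linear and random-intercept models,
    the standard empirical comparators (Fisher's exact test and the Wald
    difference-in-proportions interval), a screening pipeline emitting
    per-outcome signal tables, and a synthetic-trial generator with
    operating-characteristic simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    lme4,
    lmerTest
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
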