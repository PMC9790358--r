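Package: predinfer
Title: Predictive-Inference Task Simulation and Change-Point Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the circular predictive-inference ("coin and bucket")
    task used to study learning under volatility. Simulates the task's
    generative process (Gaussian outcomes around a latent mean that is
    resampled at a fixed hazard rate), runs a reduced quasi-optimal Bayesian
    observer yielding change-point probability, relative uncertainty and
    normative learning rates, simulates synthetic agent cohorts with
    group-dependent updating policies, derives trialwise empirical learning
    rates and standardised confidence with the standard exclusion and binning
    rules, fits the per-subject action, confidence and action-confidence
    coupling regressions, and provides the group-comparison battery
    (rank-sum with Z and Wilcoxon r, Student/Welch t with Cohen's d,
    Huynh-Feldt-corrected mixed ANOVA, Welch-James approximate degrees of
    freedom test, Kruskal-Wallis with Bonferroni post-hocs, and covariate
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
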