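Package: perprotocol
Title: Per-Protocol Effect Estimation in Randomized Trials with Imperfect Adherence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating per-protocol causal effects in two-arm
    randomized trials with imperfect adherence. Derives time-fixed adherence
    exposures from longitudinal pill-taking records under configurable
    (days-per-week, fraction-of-weeks) protocols, reproduces standard
    baseline-characteristics testing (Pearson chi-square, Kruskal-Wallis),
    implements stacked generalization (super learner) with nonnegative
    least squares meta-weights, and estimates risk differences and risk
    ratios by cross-fit augmented inverse probability weighting (AIPW),
    targeted maximum likelihood (TMLE), g-computation, inverse probability
    weighting, and unadjusted contrasts. Includes a calibrated synthetic
    trial generator, modelled on a preconception aspirin trial, with
    Monte-Carlo oracles for the true estimands so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    splines,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
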