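Package: dietRS
Title: Microbiome and Metabolome Analysis for Resistant-Starch Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for two-diet, repeated-measures feeding
    trials that profile the fecal microbiome and metabolome. Implements
    Hill-number alpha-diversity and 1-CqN beta-diversity profiles over a
    continuum of order q, Bayesian-multiplicative (CZM) zero replacement and
    the centered log-ratio transform for compositional count data, a
    differential-testing cascade combining per-timepoint t-tests,
    random-intercept linear mixed models, Storey q-values and a dual
    p/q significance criterion, class-level MANOVA, PLS-DA via NIPALS with
    VIP scoring and K-fold cross-validation, and deterministic targeted
    summaries (short-chain fatty acid totals and ratios, redox pairs, diet
    proximate formulas). A synthetic-data generator emulates the trial
    design (two groups, two timepoints, replicate collections with
    missingness, planted group effects) so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
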