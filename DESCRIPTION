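Package: lookaway
Title: Oculomotor Disgust Avoidance and Reinforcement Learning Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for a placebo-controlled crossover study of
    oculomotor disgust avoidance. Converts trial-level eye-tracking fixations
    over two lateral image areas of interest into dwell-time proportions and
    neutral-minus-disgust avoidance scores, applies the missing-data trial
    filter, fits Rescorla-Wagner/softmax reinforcement-learning models (single
    and dual learning-rate variants) to two-armed reversal-bandit choices by
    multi-start maximum likelihood, quantifies evidence for null hypotheses
    with Akaike-weight evidence ratios and BIC-approximated Bayes factors, and
    reproduces the trial-level linear mixed-model inference structure with
    participant random intercepts, post hoc drug-difference models, per-trial
    paired tests with Holm-Bonferroni correction, and a synthetic-data
    generator with known ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
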