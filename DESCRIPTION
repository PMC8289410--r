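Package: serialdep
Title: Serial Dependence and Choice-History Biases in 2AFC Perceptual Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of serial dependence in two-alternative
    forced-choice (2AFC) perceptual decisions. Provides a closed-loop generator
    of a biased-prior, one-up/two-down staircase location-discrimination
    paradigm; synthetic observers driven by a choice-history logistic decision
    model with lapses; maximum-likelihood psychometric fitting (cumulative
    Gaussian with lapse rate), likelihood-ratio pseudo-R-squared screening and
    point-of-subjective-equality (PSE) shift estimation; and a choice-history
    logistic regression that dissociates the (typically repulsive) influence of
    prior stimuli from the (typically attractive) influence of prior choices.
    Group-level statistics (pooled t-tests, Cohen's d with noncentral-t
    confidence intervals, Pearson correlations, a times-two Bonferroni policy
    for the two history coefficients) and a full analysis pipeline with
    exclusion bookkeeping are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
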