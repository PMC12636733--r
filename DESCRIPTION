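Package: gazetrade
Title: Modelling the Trade-Off Between Learned and Perceived Information in Gaze-Based Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how decisions combine values learned by trial and
    error with evidence gathered by eye fixations. Implements a generative
    gather/look/choose agent for a two-armed bandit whose options pair a
    reward-predictive colour with a ring of twelve Landolt Cs, temporal-difference
    learning of colour values with an experience-adaptive learning rate, a
    binomial posterior over the number of upward-facing Cs, a joint likelihood of
    fixation sequences and choices, hierarchical empirical-Bayes fitting by
    iterative importance sampling with integrated-BIC model comparison,
    fixation-report parsing with interest-area assignment and repeat-fixation
    filtering, a synthetic-cohort generator with known ground truth, and
    regression-based trade-off analyses (colour-by-gaze interaction, relative-use
    indices, model-data correspondence summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
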