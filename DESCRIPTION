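Package: sisterdiv
Title: Sister-Clade Diversification Contrasts and Rate-Shift Tests for
    Gall-Inducing Insects
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of diversification in gall-inducing versus
    non-galling insect sister clades. Implements Equal Rates Markov (ERM)
    tail probabilities for diversity bipartitions with Bonferroni-corrected
    two-hypothesis tests, sister-pair contrast metrics (raw, proportional,
    log-ratio) with sample-size-dispatched exact significance tests
    (sign-permutation, exact and normal-approximation Wilcoxon signed-rank,
    exact binomial), a host-breadth specificity test based on host-plant
    MRCA ages, and maximum-likelihood birth-death rate-shift detection on
    richness trees (fixed versus flexible single-shift models with LRT, and
    a stepwise AIC multi-shift search). Includes seeded simulators for ERM
    splits, rate-biased sister-pair tables, and birth-death trees with
    optional rate shifts, collapsible to richness trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'core_io.R'
    'erm.R'
    'contrasts.R'
    'rate_shift.R'
    'synthetic.R'
    'pipeline.R'
    'sisterdiv-package.R'
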