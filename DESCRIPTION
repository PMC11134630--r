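Package: evoiso
Title: Pre- and Postmating Reproductive Isolation in Replicated Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of reproductive isolation arising in
    replicated experimental evolution, from mate-choice assays to
    transcriptome divergence. Provides assortative-mating statistics
    (Yule's Q and coefficient of colligation Y, exact Fisher tests),
    compositional analysis of cuticular hydrocarbon (CHC) profiles
    (centred log-ratio transform, PCA, per-compound two-way ANOVA),
    diallel-cross compatibility analysis (mid-parent expectations, exact
    one-tailed Wilcoxon rank-sum tests, design-respecting permutation
    tests), negative-binomial GLM likelihood-ratio tests for
    among-replicate expression divergence with empirical-Bayes dispersion
    shrinkage, a pairwise-correlation heterogeneity statistic over
    replicate expression-change vectors with resampling nulls, gene-set
    over-representation tests, and a seeded synthetic-data generator for
    every modality so that all analyses are testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
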