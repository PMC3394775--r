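Package: rulemine
Title: Rule-Based Evolutionary Classification and Gene Prioritization for
    Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Induces human-readable decision lists over gene-expression
    intervals with two evolutionary learners: an iterative rule learner that
    evolves one rule per covering step with a genetic algorithm, and a
    Pittsburgh-style learner that evolves whole rule sets. Provides three
    feature-selection methods (univariate F-statistic ranking, correlation-based
    feature selection with a greedy best-first search, and random-forest
    Gini-importance ranking), seed ensembles with majority voting,
    rule-frequency and consensus gene rankings, a two-level external
    cross-validation harness with Friedman average-rank and Holm post-hoc
    comparisons, a pointwise-mutual-information literature-mining score with a
    permutation null, and a synthetic-data generator with planted informative
    genes and planted gene-disease associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    e1071
Config/testthat/edition: 3
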