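Package: progsig
Title: Cross-Cohort Prognostic Power of Gene-Set Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cumulative prognostic power of gene sets from
    multi-cohort transcriptomic meta-sets. Trains linear soft-margin support
    vector machine classifiers on the expression of gene subsets, discards
    classifiers that fail an AUC filtration cascade on held-out cohorts,
    evaluates survivors on an independent testing cohort (ROC/AUC and
    Kaplan-Meier log-rank separation of predicted risk groups), and assesses
    significance by Monte Carlo label permutation under three strategies,
    reporting the most conservative p-value. Includes a synthetic meta-set
    generator with a planted linear risk signature so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
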