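Package: feedbackMR
Title: Bidirectional Mendelian Randomization with Feedback Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of bidirectional causal effects between two continuous
    phenotypes from one-sample individual-level data using Mendelian
    randomization. When two traits each causally affect the other, the induced
    feedback loop biases naive unidirectional instrumental-variable estimators.
    This package implements the feedback-aware BiRatio (cross-instrument
    adjusted inverse-variance weighted ratio) and BiLIML (limited information
    maximum likelihood k-class) estimators alongside their naive
    unidirectional counterparts, a generative simulation engine for the
    unidirectional and bidirectional structural models under Hardy-Weinberg
    genotypes, and a replicate benchmark harness reporting median estimates,
    median absolute bias and relative median absolute bias under strong and
    weak instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
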