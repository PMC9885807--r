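Package: vitroscreen
Title: Screening Strategies for In Vitro Systematic Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for citation screening in systematic reviews of in vitro
    research. Implements dictionary-based screening by counting regular
    expression matches in titles/abstracts or full text with ROC-calibrated
    inclusion thresholds; a tri-gram bag-of-words linear support vector
    machine trained by stochastic gradient descent with recall-targeted
    score thresholds and an error-correction retraining loop; diagnostic
    accuracy statistics (sensitivity, specificity, precision, Euclidean
    distance to the perfect operating point, AUC) and corpus-scale
    projection arithmetic; dual-reviewer reconciliation with third-reviewer
    arbitration and gold-standard construction; and a seeded synthetic
    corpus generator so every pipeline stage can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    stringi,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
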