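Package: pbfaudit
Title: Audit Targeting and Verification Cost Analysis for Performance-Based Financing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting health-facility audit targets in
    performance-based financing (PBF) programs. Simulates facility-quarter
    reporting panels with configurable over-reporting behavior, computes
    bonus-based over-reporting labels at a relative-excess threshold,
    implements random, stratified, prior-offender and classifier-ranked
    audit sampling strategies, evaluates their detection yield by Monte
    Carlo, benchmarks naive Bayes, logistic regression, support vector
    machine and random forest classifiers under cross-validation, and
    quantifies verification cost-effectiveness with a linear audit cost
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    glmnet,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
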