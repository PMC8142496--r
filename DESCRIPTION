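Package: phosml
Title: Phosphorylation-Site Prediction from Sequence, Structural and
    Functional Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts serine, threonine and tyrosine phosphorylation sites
    from protein sequences. Candidate sites are represented as 21-residue
    windows and encoded under five feature schemes (physicochemical scales,
    one-hot sequence identity, structural profiles, and protein-level
    functional-term and annotation membership). Features pass through a
    two-stage filter -- greedy minimum-redundancy maximum-relevance ranking
    within each feature category followed by symmetrical-uncertainty
    ranking of the pooled survivors -- before training random-forest or
    RBF-kernel support-vector classifiers. Includes stratified
    cross-validation, a full confusion-matrix/ROC evaluation suite, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
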