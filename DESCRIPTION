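Package: hydrosite
Title: Atom-Level Hydrolysis Site Prediction and Metabolite Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hydrolysis sites of metabolism (SOMs) in environmental
    organic chemicals and enumerates their hydrolysis products. Per-atom
    classifiers (N-, O-, C- and Global-Hydrolysis) are trained on circular
    atomic-environment fingerprints plus interpretable atomic descriptors,
    passed through a variance/ANOVA-F/t-test feature-selection cascade, and
    coupled to a knowledge-based reaction-SMARTS rule engine that generates,
    scores and ranks hydrolysis metabolites. Includes a synthetic reaction
    corpus generator with per-atom ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    ranger,
    rpart,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
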