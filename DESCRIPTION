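Package: trpdesign
Title: Model-Guided Combinatorial Promoter Engineering of Tryptophan Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A design-build-test-learn toolkit for combinatorial promoter
    engineering of the yeast tryptophan pathway. Scores candidate genes for
    over- or under-expression from parsimonious flux balance analysis of a
    stoichiometric model, designs and audits combinatorial promoter libraries
    with Monte Carlo coverage estimates, converts biosensor plate-reader time
    series into quality-controlled GFP synthesis rates, fits a Bayesian
    stacked ensemble of regression learners mapping promoter genotypes to
    synthesis rates, and ranks unseen designs by predicted mean or expected
    improvement. Includes a synthetic-data generator emulating the
    statistical structure of a biosensor screen so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    randomForest,
    ranger,
    xgboost,
    e1071,
    caret,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
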