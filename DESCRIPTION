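Package: opswatch
Title: Regulatory-Status Modelling and Composite Toxicity Watch Lists for
    Organophosphorus Pesticides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for prioritizing organophosphorus pesticides (OPs)
    for regulatory attention. Builds multi-class machine-learning models of
    regulatory status (banned/restricted/unrestricted) from molecular
    descriptor tables with Pearson redundancy pruning and random-forest
    importance ranking; scores compounds and their environmental
    transformation products on 24 toxicity indicators by entropy weighting
    coupled with TOPSIS multi-criteria decision analysis; and bins the
    composite toxicity scores into a four-level special-attention watch
    list using standard-deviation intervals. Includes a synthetic-data
    generator with plantable class signal and toxicity shifts so every
    stage is testable without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    xgboost,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
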