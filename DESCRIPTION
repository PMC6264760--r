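Package: ermqsar
Title: QSAR Model Building by Enhanced Replacement Method Descriptor Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR) models
    for small-molecule activity data by multiple linear regression on compact
    molecular-descriptor subsets. Implements descriptor-pool pruning (constant
    and intercorrelated columns), descriptor-subset selection by minimization
    of the regression standard deviation via exhaustive full search, the
    Replacement Method and the Enhanced Replacement Method, leave-one-out
    cross-validation (Q2) and external test-set validation, together with a
    planted-model synthetic descriptor-pool generator and an embedded
    flavonoid vasorelaxant activity benchmark (EC50 to pEC50).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
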