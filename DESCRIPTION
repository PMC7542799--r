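Package: domrank
Title: Dominance Rank Metrics and Competitive Regime Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a rank-related trait in a social animal
    group is shaped by density-dependent or density-independent competition.
    Builds monthly, sex-specific win-loss matrices from dyadic agonistic
    interactions, infers the linear dominance order that minimizes entries
    below the matrix diagonal, converts orderings into simple ordinal and
    proportional ranks, and compares the two metrics' ability to predict
    traits via a three-model (ordinal, proportional, null) AIC procedure with
    exact binomial and Fisher tests on the resulting tallies. A longitudinal
    multi-group simulator generates agonistic bouts, hierarchies and traits
    under explicitly density-dependent or density-independent resource
    regimes, enabling end-to-end validation of the comparison procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    MASS,
    survival
Suggests:
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
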