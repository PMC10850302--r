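Package: consensustox
Title: Consensus (Q)SAR Toxicity Models with Pareto-Front Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted consensus models from panels of binary
    (Q)SAR toxicity predictors that each carry their own applicability
    domain.  Component predictions (active, inactive, or out-of-domain)
    are combined by majority voting, by four statistically weighted
    schemes (balanced accuracy, modified score1, predictivity, and
    modified predictivity), or by k-nearest-neighbour distance
    weighting in descriptor space.  Every subset of component models is
    enumerated and evaluated, Pareto fronts over coverage and modified
    predictivity identify the non-dominated consensus models, and a
    bootstrap analysis tests whether the composition of the front is a
    chance result.  A synthetic panel generator with controllable
    sensitivity, specificity, coverage, prevalence, and inter-model
    error correlation supports testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
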