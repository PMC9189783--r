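Package: fermopt
Title: Design-of-Experiments, Response-Surface and Neural-Network Optimization of Fermentation Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative side of microbial fermentation medium
    development: two-level factorial and central composite rotatable designs with
    coded/actual level mapping, first-order screening fits and path-of-steepest-ascent
    candidates, full second-order response-surface regression with lack-of-fit ANOVA,
    a Levenberg-Marquardt-trained feed-forward neural network as an alternative
    response model, a seven-metric model-comparison suite, desirability-based
    optimum location with a confirmation-experiment rule, logistic and modified
    Gompertz fermentation kinetics with yield-coefficient accounting, strain-screening
    and aqueous two-phase purification bookkeeping, and seeded synthetic-data
    generators so the whole pipeline is testable at desk scale. Ships the published
    protease-production study tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
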