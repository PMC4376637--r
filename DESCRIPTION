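Package: effdisc
Title: Effort and Delay Discounting Models with Bayesian Model Comparison
Version: 0.1.0
Authors@R: person("effdisc", "maintainers", email = "effdisc@example.org", role = c("aut", "cre"))
Description: Parametric discounting models (hyperbolic, linear, quadratic,
    sigmoidal, two-parameter power) for choices between rewards carrying
    physical-effort or temporal-delay costs, with a softmax choice rule,
    variational-Laplace Bayesian fitting returning a free-energy approximation
    to the log model evidence (decomposed into accuracy and complexity),
    random-effects group Bayesian model selection (model frequencies and
    exceedance probabilities), a PEST adaptive-staircase engine with
    psychometric indifference-point estimation and concavity classification,
    and a synthetic-cohort generator that emulates the discriminative
    two-alternative choice designs the pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
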