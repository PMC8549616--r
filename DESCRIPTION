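Package: multistress
Title: Multistressor Life-History Analysis for Resurrected Daphnia Populations
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing factorial multiple-stressor common-garden
    experiments on clonal zooplankton populations separated in time.
    Provides a synthetic-data generator with known ground truth, per-batch
    trait standardization, mixed-model trait ANOVAs with a genotype random
    effect nested in population, parametric (Weibull) survival analysis,
    decomposition of trait change across historical transitions into
    plasticity, genetic evolution and evolution of plasticity, additive
    null-model classification of stressor interactions (additive,
    synergistic, antagonistic), and ternary life-history trade-off
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
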