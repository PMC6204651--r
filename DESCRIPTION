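Package: aarchron
Title: Amino Acid Racemization Chronology and Death-Assemblage Analysis of
    Sediment Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building shell-based chronologies of marine sediment
    cores and analysing the molluscan death assemblages they contain.
    Calibrates amino acid racemization (AAR) ages against radiocarbon-dated
    shells by fitting a grid of kinetic models (simple and constrained
    power-law, apparent parabolic, and time-dependent reaction kinetics, each
    with lognormal or gamma age uncertainty) selected by BIC; converts D/L
    ratios to calendar ages with prediction intervals; summarises
    time averaging per depth increment with a lognormal calibration-error
    correction; implements a minimum-number-of-individuals counting protocol
    for bivalves, gastropods and polyplacophorans with functional-trait
    aggregation; and wraps the community statistics used in death-assemblage
    studies (effective species richness with resampling confidence intervals,
    Wilcoxon unit contrasts, PERMANOVA, NMDS, forward-selection RDA). A
    seeded synthetic-core generator with known ground truth lets the whole
    pipeline run and be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vegan,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aarchron-package.R'
    'assemblage.R'
    'calibration-data.R'
    'calibration-fit.R'
    'community.R'
    'io.R'
    'kinetics.R'
    'predict.R'
    'synthetic-core.R'
    'time-averaging.R'
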