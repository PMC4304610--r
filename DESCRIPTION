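Package: vaporisk
Title: Probabilistic Exposure and Margin-of-Exposure Assessment for
    E-Cigarette Liquid Constituents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative risk assessment of constituents of
    e-cigarette liquids (nicotine, solvents such as glycerol and
    propylene glycol, and flavour compounds).  Provides risk-function
    distribution objects with shifting and truncation, distribution
    fitting with Kolmogorov-Smirnov model selection and an empirical
    resampling fallback for low-incidence analytes, Latin Hypercube
    Monte-Carlo propagation through a daily-exposure model, margin of
    exposure (MOE) statistics against a packaged toxicological
    threshold registry, standardized-regression sensitivity analysis,
    and method-validation statistics for quantitative NMR assays
    (calibration, LOD/LOQ, recovery, method comparison).  A
    synthetic-data generator produces study-shaped concentration
    tables so the whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
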