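Package: secondair
Title: Secondhand Exposure Modeling for E-Vapor Aerosol Constituents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates potential non-user (bystander) exposure to chemical
    constituents exhaled during electronic vapor product (EVP) use. Provides a
    synthetic generator for four-period crossover exhaled-breath studies with
    paired sham/product collections and detection-limit censoring; a linear
    mixed-effects ANCOVA that estimates sham-corrected least-squares means per
    product and converts them to per-milligram emission factors; a transient
    well-mixed (single-box) indoor air model with equilibrium vapor/particle
    partitioning; and scenario-level intake calculations that compare EVP
    sources against cigarette sidestream smoke and occupational exposure
    limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
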