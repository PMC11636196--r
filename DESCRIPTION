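Package: fsera
Title: Form-Specific Prospective Environmental Risk Assessment for
    Engineered Nanomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prospective, form-specific environmental risk
    assessment of engineered nanomaterials such as graphene-based
    materials (pristine graphene, graphene oxide, reduced graphene
    oxide).  Disaggregates total production time series into material
    forms through row-stochastic market share matrices, propagates
    yearly masses through a dynamic probabilistic material-flow model
    (Monte Carlo over uncertain transfer coefficients) into technical
    and environmental compartments, converts releases into predicted
    environmental concentration (PEC) distributions for freshwater and
    soils, derives predicted no-effect concentrations (PNEC) either by
    probabilistic species sensitivity distributions (HC5 by Monte
    Carlo) or by assessment factors, and characterises risk as
    distributions of the risk characterisation ratio RCR = PEC/PNEC.
    Includes a synthetic-data generator with known analytic ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
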