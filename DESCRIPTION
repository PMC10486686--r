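Package: strawnir
Title: Chemometric Cultivar Phenotyping from FT-NIR Strawberry Spectra
Version: 0.1.0
Authors@R:
    person("strawnir", "developers", email = "strawnir@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for near-infrared (NIR)
    phenotyping of strawberry fruit quality. Generates synthetic FT-NIR
    spectra linked to laboratory quality panels (soluble solids, titratable
    acidity, vitamin C, anthocyanins, phenolic acids) for four cultivars,
    and implements the full chemometric workflow: spectral preprocessing
    (SNV, MSC, Savitzky-Golay derivatives, block scaling), principal
    component analysis with confidence-ellipse summaries, low- and mid-level
    multiblock data fusion with back-reconstruction of original-variable
    contributions, duplex sample-set partitioning, venetian-blinds
    cross-validation, PLS-DA classification with ROC-based threshold
    selection, and one-way ANOVA with Tukey HSD compact letter displays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
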