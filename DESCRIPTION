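Package: mycophenom
Title: Quantitative Phenomics of Filamentous Fungal Fermentation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify and model the link between filamentous fungal
    strain phenotypes and secreted protein titres in submerged culture.
    Includes seeded generators for synthetic pellet micrographs and
    strain-by-inducer phenotype tables; pellet macromorphology measurement
    (area, Feret calipers, solidity, aspect ratio and the dimensionless
    morphology number) from grayscale images; solid-culture phenotype
    statistics (radial growth rate, stress growth coefficients, hyphal growth
    unit, biomass-normalized protein, control comparisons); ordinary least
    squares with two-stage backward elimination (p > 0.15 in the first round,
    p > 0.05 thereafter); and titre prediction under hypothetical percentage
    changes in strain parameters, tied together by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
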