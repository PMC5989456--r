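Package: bifidshunt
Title: Fermentation Physiology of Bifidobacterium on Milk Oligosaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of Bifidobacterium longum subsp. infantis
    fermentation of milk carbohydrates (galactose, lactose, and the human milk
    oligosaccharide tetrasaccharides LNT and LNnT). Provides a forward and
    inverse stoichiometric model of the fructose-6-phosphate phosphoketolase
    ("bifid shunt") pathway including the pyruvate-formate-lyase branch,
    three-parameter sigmoidal growth-curve fitting for microplate OD600 data,
    external-standard HPLC calibration with sugar-consumption and
    carbon-recovery accounting, endproduct-ratio statistics (ANOVA with Tukey
    HSD, PCA, Ward hierarchical clustering), delta-delta-Ct relative gene
    expression, and a synthetic-data generator so the full pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    minpack.lm,
    ape,
    car,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
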