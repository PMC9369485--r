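Package: soilsorb
Title: Factorial Analysis of Heavy-Metal and Mineral-Sorbent Effects on Soil Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of two-factor soil
    ecotoxicology experiments in which heavy-metal contamination (Cu, Ni, Zn)
    is crossed with mineral or carbonaceous sorbent amendments. Implements the
    colony development index (CD) and ecophysiological diversity index (EP)
    computed from daily colony-emergence profiles, relative impact factors for
    metals and sorbents, balanced two-way analysis of variance with eta-squared
    effect contributions and Tukey HSD compact letter displays, Pearson
    correlation screens, principal component analysis, and clustered heat maps
    of impact matrices. Ships the reference greenhouse dataset (microbial
    counts, seven soil-enzyme activities, sunflower yield, and SPAD greenness)
    as plain-text fixtures, together with a seeded synthetic-experiment
    generator for power, type-I error, and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
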