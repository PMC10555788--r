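Package: sibmr
Title: Within-Sibship Mendelian Randomization Models and Family-Based Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for family-based causal inference with genetic instruments:
    population and within-sibship association models (linear and Cox
    proportional hazards on an age timescale) with sibship-clustered sandwich
    standard errors, polygenic score construction with greedy linkage
    disequilibrium clumping, Wald-ratio and inverse-variance-weighted
    Mendelian randomization estimators with delta-method standard errors,
    shrinkage (population-to-within-sibship attenuation) statistics and
    fixed-effects meta-analysis. Includes a multi-sibling cohort simulator
    with known causal structure implementing population stratification,
    assortative mating and indirect parental genetic effects, so every
    estimator has a parameter-recovery test with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    sandwich,
    igraph,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
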