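Package: aavdoe
Title: Mixture and Response-Surface Design of Experiments for rAAV
    Production Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing recombinant adeno-associated virus
    (rAAV) triple-transfection production with sequential design of
    experiments. Generates D-optimal constrained mixture designs over
    the three plasmid mass fractions (pHelper, pRepCap, pGOI) by
    Fedorov point exchange, builds two-factor face-centered central
    composite designs (FCCD) for total DNA and transfection-reagent
    ratio, fits Scheffe quadratic mixture models and second-order
    response-surface models with whole-model ANOVA, and locates
    multi-response optima with Derringer desirability functions over
    log volumetric productivity, percent full capsids and cell
    viability. Includes a synthetic response-surface generator with
    gene-of-interest archetypes so the full mixture-design to FCCD
    pipeline can be exercised and validated in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
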