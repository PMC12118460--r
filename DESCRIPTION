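Package: anthosphere
Title: Community Assembly Analysis for Flower and Pollinator Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing amplicon sequence variant (ASV) count
    tables from flower (anthosphere) and pollinator microbiome surveys.
    Implements the read/taxon filtering rules common to 16S flower
    surveys, alpha diversity with nonparametric group comparisons,
    Bray-Curtis beta diversity with sequential PERMANOVA, multivariate
    dispersion and constrained ordination, occupancy-abundance core
    detection by the elbow criterion, Sloan neutral community model
    fitting, and a pollinator-to-flower bacterial transfer index.
    Includes seeded Dirichlet-multinomial community simulators with
    known ground truth for validating every analysis stage, and a
    configuration-driven pipeline that writes a structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    ape,
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
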