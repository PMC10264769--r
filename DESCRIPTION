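Package: hydrotrait
Title: Hydraulic Trait Analysis for Flowers and Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative hydraulic trait analysis of flowers and
    leaves: anatomy-derived hydraulic indices (hydraulically weighted vessel
    diameter, vessel frequency, Hagen-Poiseuille theoretical conductivity,
    intervessel pit morphometrics, stomatal density under a border-counting
    rule), minimum diffusive conductance from bench drying curves with
    Arden Buck vapour pressure deficits, pressure-volume parameter extraction
    (saturated water content, osmotic potential at full turgor, turgor loss
    point, absolute capacitance) on a dry-mass basis, phylogenetic independent
    contrasts with through-origin contrast regression, comparative statistics
    (paired t-tests, one-way ANOVA with LSD letters, OLS and standardized
    major axis regression, PCA with convex-hull trait-space overlap), a
    synthetic study generator with known ground truth, and a pipeline
    orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
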