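Package: phiflux
Title: Intracellular pH Recovery Analysis and Mechanistic Simulation of
    Ammonium-Prepulse Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of BCECF ratiometric
    intracellular pH (pHi) recordings from ammonium-prepulse experiments:
    nigericin high-potassium calibration, conversion of F495/F440 ratios to
    pHi, Henderson-Hasselbalch buffering capacity from NH4Cl washout, net
    base uptake as a function of pHi from windowed regression, final plateau
    pHi, and the group-comparison statistics used for genotype contrasts
    (repeated-measures two-way ANOVA, Mann-Whitney U, slope comparison,
    paired t with Bonferroni correction). Includes a mechanistic simulator
    of transporter-driven pHi regulation (Na+/HCO3- co-transport and Na+/H+
    exchange with open-system CO2/HCO3- buffering) that generates ground
    truth cohorts for pipeline validation, and quantification of allelic
    expression imbalance from chromatogram peak heights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
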