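Package: EpiBarrier
Title: Quantitative Readouts for Bronchial Epithelial Barrier Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computation and simulation of the quantitative readouts used to
    characterize bronchial epithelial barrier cultures: transepithelial
    electrical resistance (TEER) and apparent permeability coefficients
    (Papp) from insert assays, real-time impedance cell-index kinetics,
    apical-membrane versus cytoplasm localization scoring of target-protein
    staining in confocal z-stacks, K-means segmentation of junctional
    immunostaining, ratiometric (BCECF-type) intracellular-pH calibration,
    and the associated group-comparison statistics (one-way ANOVA with
    Dunnett's many-to-one test, two-way ANOVA with Bonferroni-adjusted
    contrasts). A synthetic-data generator with known ground truth emulates
    every input so the whole pipeline is testable without microscope or
    plate-reader data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
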