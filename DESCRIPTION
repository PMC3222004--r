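Package: qctlung
Title: Quantitative CT Densitometry of the Lung
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise quantitative computed tomography (qCT) analysis of
    lung aeration. Converts Hounsfield units to tissue density, computes
    total lung mass and volume, partitions lung mass into aeration
    compartments (hyperaerated, normally, poorly and nonaerated), refines
    aerated lung boundaries against partial-volume effects with a -350 HU
    threshold band, derives robust (CLSI C28-A3 style) and nonparametric
    reference intervals for lung mass, assesses method agreement with
    percent-difference Bland-Altman statistics, classifies posttraumatic
    lung dysfunction into atelectasis versus consolidation by mass
    cut-offs, and ships synthetic thoracic phantom and cohort generators
    with exact ground-truth bookkeeping for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
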