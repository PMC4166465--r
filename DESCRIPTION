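Package: cytobead
Title: Simulation and Automated Interpretation of Combined Cell- and
    Microbead-Based ANCA Immunofluorescence Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated interpretation of multiplexed
    anti-neutrophil cytoplasmic antibody (ANCA) assays that combine
    indirect immunofluorescence on ethanol-fixed neutrophils with
    antigen-coated microbead immunoassays in one reaction environment.
    Provides a synthetic well generator with ground truth (neutrophil-like
    cells with cytoplasmic or perinuclear staining, size-multiplexed
    9/12/15 micrometre bead populations, concentration-dependent surface
    halos, and a camera noise model), bead and cell detection with halo
    quantification and staining-pattern classification, five-parameter
    logistic master-curve calibration with two-point run recalibration,
    single-dilution endpoint-titer estimation, and the agreement
    statistics used to validate such assays (Cohen's kappa, weighted
    kappa, McNemar's exact test, ROC analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
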