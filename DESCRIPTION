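Package: iraePET
Title: Quantitative FDG-PET Imaging Biomarkers of Immune-Related Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-level quantification of 18F-FDG PET uptake for detecting and
    monitoring immune-related adverse events (irAE) in patients receiving
    immune-checkpoint inhibitors. Computes standardized uptake values (SUV) from
    activity volumes, extracts organ-masked SUV percentile profiles (SUV_X%),
    selects the AUROC-maximizing percentile per organ, derives Youden-optimal
    cutoffs, builds normative reference bands from irAE-free baseline scans,
    and flags longitudinal excursions relative to clinical irAE dates. Includes
    a synthetic PET phantom cohort generator (diffuse thyroiditis-like and
    focal colitis/pneumonitis-like inflammation patterns) so the full analysis
    is testable without clinical images, plus segmentation-quality metrics
    (Dice coefficient, average symmetric surface distance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'imaging-ops.R'
    'imaging-io.R'
    'quant.R'
    'phantom.R'
    'uptake.R'
    'cohort.R'
    'biomarker.R'
    'normative.R'
    'plots.R'
    'pipeline.R'
    'iraePET-package.R'
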