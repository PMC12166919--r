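Package: wedgecal
Title: Radiochromic Film Calibration from Physical-Wedge Dose Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end radiochromic film (EBT3) dosimetry pipeline built
    around calibration from the lateral dose gradient of a physical wedge.
    Reads and reduces flatbed-scanner TIFF stacks (median, average, adaptive
    Wiener filtering), computes net optical density with propagated
    uncertainty, extracts wedge netOD profiles by gradient-based field
    segmentation, and fits the two-term power-law dose response with a fixed
    exponent, including single-gradient, extrapolated and concatenated
    multi-gradient calibrations. A conventional multi-strip uniform-field
    calibration with a full experimental/fit uncertainty budget serves as the
    benchmark, and a seeded synthetic scan generator replicates the study
    geometry so every stage is testable without real films.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'filters.R'
    'scan-io.R'
    'densitometry.R'
    'calibration.R'
    'profile-ops.R'
    'wedge.R'
    'synthetic.R'
    'study-io.R'
    'study-analysis.R'
    'cli.R'
    'wedgecal-package.R'
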