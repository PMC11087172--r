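Package: acrct
Title: Automated ACR CT Phantom Image-Quality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital simulation and automated analysis of the American College
    of Radiology (ACR) CT accreditation phantom. Renders voxelized scans of the
    head phantom (with optional body ring) under controllable degradations
    (noise, blur, radial cupping, per-material HU bias, geometric scale error,
    misalignment), localizes the phantom and places the standard ROIs, computes
    the five ACR image-quality metrics (contrast-to-noise ratio, Hounsfield-unit
    accuracy, uniformity, image scaling, bar-pattern spatial resolution), and
    scores metric tables against configurable ACR pass/minor/major criteria with
    deviation summaries, verdict tallies, baselines, and machine comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
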