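Package: her2scan
Title: Continuous Motion-Blur Slide Scanning Simulation and HER2 Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for continuous ("blurry")
    whole-slide scanning of HER2-stained tissue microarrays. Generates
    synthetic TMA slides with score-graded membrane staining, simulates
    zigzag stage motion with rectangular motion-blur kernels, stitches the
    resulting frame stream into whole-slide mosaics via consecutive-frame
    correlation and square-wave motion-model fitting, crops and labels
    tissue cores against a layout manifest, classifies HER2 scores (0, 1+,
    2+, 3+) with a Fourier-domain spectral network trained on multi-scale
    image stacks, and aggregates repeat-scan predictions with
    confidence-based schemes including indeterminate-rate analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
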