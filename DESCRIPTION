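Package: ldhgrade
Title: Rule-Based Grading of Lumbar Disc Herniation in Sagittal T2 MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes lumbar vertebrae and intervertebral discs in single
    mid-sagittal T2-weighted spine images and grades each disc as normal,
    bulge, protrusion or extrusion from five geometric-intensity indicators
    (protrusion distance, protrusion area, length ratio, area ratio and mean
    gray level). The pipeline covers morphological preprocessing, band-pass
    multithreshold vertebra segmentation with contour screening, caudal
    vertebra handling via contour poles, posterior demarcation lines, disc
    segmentation, spinal-canal continuity testing, and a majority-vote
    classifier with a fixed indicator priority for ties. A synthetic
    spine-phantom generator with exact ground truth makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
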