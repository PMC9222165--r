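Package: grafhip
Title: Automated Graf Standard-Plane Scoring and Angle Measurement for
    Infant Hip Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automated Graf-method analysis of coronal infant hip
    ultrasound. Given per-structure bounding boxes for the ilium, labrum,
    bony rim, and lower limb of the os ilium (from any plugged-in detector,
    the bundled heuristic detector, or synthetic ground truth), the package
    filters and validates detections, scores how close each video frame is
    to the Graf standard plane using confidence, height-width ratio, and
    image-moment tilt terms, segments structures by maximum-entropy
    thresholding, localizes the four Graf landmarks, constructs the
    baseline, bony roof, and cartilage roof lines, and measures the alpha
    and beta angles with type I/II classification. A synthetic hip-phantom
    generator with exact ground truth supports end-to-end testing, and
    agreement statistics (MAE, Bland-Altman limits, ICC(2,1), Cohen's
    kappa) support method-comparison reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
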