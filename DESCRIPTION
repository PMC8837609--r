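Package: ivdquant
Title: Quantitation and Grading of Lumbar Intervertebral Disc Degeneration from Segmented Sagittal MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes signal-intensity and geometric degeneration parameters of
    lumbar intervertebral discs from a mid-sagittal T2-weighted image paired
    with a 14-class anatomical label mask: the CSF-normalized two-peak
    signal-intensity difference, vertebral body diameter and height, average
    disc height from the central 80 percent band, disc height index, and disc
    height-to-diameter ratio. Grades degeneration by deviation of the
    signal-intensity difference from per-grade reference distributions and
    reports standardized deviations from population baselines. Includes a
    seeded synthetic spine phantom with analytic ground truth, an
    encoder-decoder semantic segmentation network with window-attention skip
    connections trained with a weighted multiclass dice loss, and evaluation
    metrics (mean dice, mean IoU, macro F1, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    RNifti,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
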