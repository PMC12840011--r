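Package: contourIOV
Title: Interobserver Variation Analysis for Multi-Observer Radiotherapy
    Delineations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies interobserver variation (IOV) in radiotherapy
    target-volume and organ-at-risk delineation. Planar contour sets from
    multiple observers are rasterized onto a common voxel grid; the package
    then computes per-structure volume statistics (mean, SD, coefficient of
    variation, range), pairwise overlap agreement (Dice, Jaccard, the
    pairwise conformity index CIpairs, mean absolute surface distance),
    lymph-node-level inclusion in the planning target volume by an
    overlap-fraction criterion, and landmark-referenced border and width
    geometry. A seeded synthetic multi-observer cohort generator with
    analytic ground truth (systematic margin bias, smooth boundary noise,
    caudal truncation, structure omission) makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
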