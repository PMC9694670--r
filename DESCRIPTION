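Package: kneeatlas
Title: Atlas-Based Fuzzy Segmentation of Knee-Joint Bone Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automatic extraction of the patella, femur and tibia from
    series of 2D knee-joint images (CT transverse or T1-weighted MR sagittal).
    Inter-series scan matching runs on entropy (or energy) measures of
    fuzziness scored with intensity-based similarity measures (normalized
    cross-correlation, gradient correlation, gradient difference). An
    11-set normalized feature atlas built from expert-annotated teaching
    series supplies seed centroids and area priors to seeded fuzzy c-means
    and fuzzy connectedness segmentation, with an area-conformity guard
    against over-segmentation, skeleton-based patella seed relocation on the
    sagittal plane, and morphological post-processing. Includes the packaged
    reference atlas and per-case Dice tables, Dice/Bland-Altman/paired-test
    evaluation, and a synthetic knee phantom generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    png,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
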