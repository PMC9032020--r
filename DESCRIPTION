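Package: resectseg
Title: Semiautomated Segmentation of Surgical Resection Cavities on
    Postoperative Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates surgical resection cavities on co-registered
    postoperative T1-weighted brain MRI using seeded, brain-mask-constrained
    best-first region growing with a tolerance criterion on the distance from
    the evolving region mean.  Implements four intensity-standardization
    variants (global/local contrast-stretch adjustment and min-max
    normalization), Gaussian preprocessing of the preoperative brain mask,
    factorial parameter-grid evaluation with the dice similarity coefficient
    and the mean quadratic discard, a 12-seed placement protocol for
    seed-robustness assessment, and an automated anatomical report that maps
    a cortical parcellation to seven anatomical areas and assigns resection
    voxels by overlap or nearest-neighbour label propagation, with
    leave-one-out cross-validated selection of the resected-area threshold.
    A synthetic-phantom generator provides co-registered test inputs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
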