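Package: segsat
Title: Segmentation Performance Saturation Analysis for 3D Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to determine how test performance of a 3D medical-image
    segmentation model saturates with training-set size. Computes per-case
    agreement metrics (Dice, Jaccard, true positive rate, mean surface
    distance, physical volumes) between reference and predicted label
    volumes, fuses cross-validation fold predictions by per-voxel majority
    vote, fits an exponential-plateau learning-curve model by nonlinear
    least squares, estimates the dataset size at which performance
    plateaus, and assesses the stability of that estimate by progressive
    dropout of the largest dataset sizes. Includes cohort-level volume
    agreement analyses (linear regression, Bland-Altman percent
    differences, paired t-tests between dataset sizes) and seeded
    synthetic generators for multi-label phantoms, controllably degraded
    predictions, and learning-curve observations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
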