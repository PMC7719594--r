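Package: ventseg
Title: Region-Augmented Distance-Regularized Level Set Segmentation of
    Brain Ventricles
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-dimensional level set segmentation for dark, weakly
    bounded structures such as the brain ventricles in CT and T1 MRI
    slices.  Implements a distance-regularized level set evolution
    (DRLSE) in which the edge-based length and area terms are replaced
    by edge-indicator-weighted region-scalable fitting (RSF) intensity
    terms, so the contour is driven by local inside/outside intensity
    fits as well as by gradients and stays numerically close to a
    signed distance function without re-initialization.  Includes a
    coordinate-wise grid search for tuning the evolution parameters
    against ground truth, a full battery of overlap and fidelity
    metrics (Dice, Jaccard, sensitivity, specificity, accuracy, PSNR,
    SSIM), synthetic ventricle and disk phantoms with sharp and weak
    boundary segments for testing, readers for PNG/TIFF/NIfTI/DICOM
    slices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    RNifti,
    tibble,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
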