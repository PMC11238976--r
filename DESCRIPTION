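Package: kpiqa
Title: Keypoint-Based Full-Reference Image Quality Assessment for CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-reference image quality assessment for 2-D grayscale medical
    images based on local image features. The quality index is the mean Hamming
    distance between the binary descriptors of keypoints matched by brute force
    between a reference and a target image; identical images score 0 and the
    index grows as quality degrades. The package bundles four binary-feature
    backends (ORB-, BRISK- and AKAZE-style detectors/descriptors plus a simple
    segment-test reference backend), SSIM and PSNR comparators, a synthetic
    head-CT phantom with a dose-dependent quantum-noise model, Gaussian-blur and
    affine degradation series, and a study driver that reproduces the validity
    (noise/blur vs SSIM) and robustness (translation/rotation/scaling) analyses
    with Pearson correlation summaries, reports and match visualizations.
    Single-frame DICOM, PNG and TIFF images are supported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
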