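# kpiqa — keypoint-based image quality assessment for CT images

`kpiqa` implements a full-reference image quality index for 2-D grayscale
medical images built on local image features. Instead of comparing pixels
(PSNR) or windowed luminance/contrast/structure statistics (SSIM), it asks
how well the *salient features* of a degraded target image still match those
of a pristine reference of the same scene:

1. detect keypoints and compute binary feature descriptors in both images
   (interchangeable backends: ORB-, BRISK- and AKAZE-style detectors plus a
   simple segment-test reference backend);
2. find corresponding keypoints by exhaustive (brute-force) matching on the
   Hamming distance between descriptors, keeping a pair only when the
   nearest-neighbour relation holds in both directions;
3. report the mean Hamming distance over the `N` matched pairs:

   `PI = (1/N) * sum_i || F_R_i - F_T_i ||_H`   (bits)

Identical images score exactly 0; noise and blur flip descriptor bits and
drive the index up; translation, rotation and scaling — which do not change
intrinsic image quality but badly degrade SSIM and PSNR — leave it largely
unchanged. The matched keypoints can also be *visualized*, showing exactly
which image structures lost their features to the degradation.

The package targets image-quality work in radiology physics (dose/protocol
optimization, reconstruction-kernel comparisons, multi-centre consistency),
where a robust, interpretable full-reference metric is needed. It is
self-contained: a synthetic head-CT phantom (skull ring, textured brain-like
interior, low-contrast inserts) and a dose-dependent quantum-noise model
(`sigma ∝ 1/sqrt(CTDIvol)`) let every analysis run without any scanner data.

## A worked example

```r
library(kpiqa)

# synthetic head-CT slice (Hounsfield units, 512x512) and a brain-window view
phantom   <- generate_head_phantom(phantom_spec(seed = 1))
reference <- to_eight_bit(phantom)   # conventional brain window C40/W80

# a low-dose acquisition of the same slice (CTDIvol 13.7 mGy vs 89.1 mGy)
low_dose <- to_eight_bit(simulate_dose_noise(phantom,
                                             dose_noise_spec(ctdi = 13.7, seed = 2)))

result <- score_pair(reference, low_dose, backend_params("orb"),
                     with_ssim = TRUE, with_psnr = TRUE)
result$pi
#> quality index (mean Hamming distance): 25.82 bits over 196 pairs [orb, L = 256]
result$ssim
#> [1] 0.59712
result$psnr
#> [1] 20.945

# the same image scores exactly zero
score_pair(reference, reference, backend_params("orb"))$pi
#> quality index (mean Hamming distance): 0 bits over 495 pairs [orb, L = 256]
```

The low-dose image lost about a tenth of its 256 descriptor bits per matched
keypoint (25.8 bits) and 304 of the reference's 500 keypoints no longer find
a mutual partner — a quantitative and a structural account of the quality
loss. `render_matches()` + `write_overlay()` draw the side-by-side keypoint/
match-line figure for the same pair.

## Studies

Two one-call drivers reproduce the full validation design on the phantom:

```r
validity   <- phantom_validity_study(seed = 1)   # 10 doses + 10 blur kernels
robustness <- phantom_robustness_study(seed = 1) # translation/rotation/scaling
write_report(validity, "results/validity")       # CSV + JSON + scatter plots
```

`phantom_validity_study()` degrades the phantom over ten dose levels
(CTDIvol 2.7–74.2 mGy) and ten Gaussian kernels (3×3 … 21×21 with
`sigma = 0.3 (k/2 - 1) + 0.8`) and correlates the index with SSIM per
backend (Pearson, alpha = 0.05); the index tracks SSIM strongly
(r ≤ −0.92 for every backend on both series) while PSNR correlates
positively with SSIM. `phantom_robustness_study()` applies the affine
battery (translations of 2–40 px, rotations of 1–45°, scalings 0.75–1.25)
and summarizes the stability of the index against SSIM's decline.

A thin command-line front end over these functions is installed at
`inst/cli/kpiqa.R` (subcommands `phantom`, `score`, `transform`, `study`,
`visualize`).

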