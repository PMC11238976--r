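---
title: "Methods: a keypoint-feature quality index and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a keypoint-feature quality index and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The index

`kpiqa` scores a degraded *target* image against a pristine *reference* of
the same scene by the mean Hamming distance between the binary descriptors
of their matched keypoints,

$$PI = \frac{1}{N}\sum_{i=1}^{N} \lVert \vec F_{R_i} - \vec F_{T_i}
\rVert_H \quad [\text{bits}],$$

where the $N$ correspondences are found by exhaustive nearest-neighbour
search over all descriptor pairs with a mutual cross-check (a pair is kept
only if each member is the other's nearest neighbour), which enforces a
one-to-one matching. No ratio test and no distance cutoff are applied; ties
are broken toward the lowest index so the matching is deterministic.

The underlying model is perceptual rather than statistical: a reader
recognizes an image through its salient local structures, so an image whose
local features still *match* those of the ideal reference retains its
diagnostic value. Bit flips in binary descriptors are a direct, bounded
measure of local appearance change. Three properties follow from the
construction:

* identical images give $PI = 0$ exactly (every matched pair is
  bit-identical);
* $0 \le PI \le L$, with $L$ the descriptor length in bits;
* $N = 0$ (no mutual matches at all) leaves the index undefined. This is
  reported as an error carrying both keypoint counts — never silently 0 or
  `NaN`, which would corrupt downstream correlation analyses. Study drivers
  record such conditions as failed and exclude them from correlations with
  a warning.

The index is reported in raw bits, matching its definition; a normalized
value $PI/L$ is carried along for cross-backend comparison but is never
used in the validation analyses.

## Feature backends

Four interchangeable backends produce keypoints and binary descriptors. No
computer-vision binding is available in this R stack, so the detectors and
descriptors are implemented in the package (C++ via Rcpp), patterned after
the published algorithm families rather than binding any particular
library. All share a FAST-9/16 segment-test corner detector (a pixel is a
corner when ≥ 9 contiguous pixels on its radius-3 Bresenham circle are all
brighter or all darker than the centre by more than a threshold), 3×3
non-maximum suppression on the summed threshold excess, and quadratic
sub-pixel localization, followed by gradient-based corner refinement
(the classic iterative `cornerSubPix` scheme) on the full-resolution image:

* **orb** — detection on an 8-level image pyramid (factor 1.2, threshold
  20), keypoints ranked per level by Harris corner response with
  geometrically decreasing per-level quotas, capped at 500 keypoints
  overall (the conventional default cap for this detector family);
  intensity-centroid orientation; steered 256-bit BRIEF-style descriptor
  whose point-pair pattern is generated once from a fixed seed by the
  package's own congruential generator and frozen.
* **brisk** — three pyramid octaves (threshold 30), a 60-point concentric
  ring sampling pattern (rings of 1/10/14/15/20 points at radii
  0/2.9/4.9/7.4/10.8, sample smoothing growing with ring radius), pattern
  orientation from long-distance point pairs, and a 512-bit descriptor
  from the 512 shortest-distance pairs.
* **akaze** — four pyramid octaves and an oriented MLDB-style 486-bit
  descriptor: over 2×2, 3×3 and 4×4 grids of an oriented patch
  (half-width 12 × scale), per-cell means of intensity and the two
  first derivatives are compared pairwise per channel
  ($3\,(6 + 36 + 120) = 486$ bits).
* **ref** — a deliberately plain single-scale backend (threshold 10, the
  conventional default for a bare segment-test detector): unoriented
  256-bit pairwise intensity-comparison descriptor with a frozen seeded
  pattern. Because it uses only intensity comparisons it is invariant to
  uniform intensity shifts, and because it has no pyramid it is fully
  verifiable against brute-force oracles. It serves as the in-repo
  comparison standard for the matcher and index tests.

Design choices that matter for reproducibility:

* **Scale selection.** Multi-scale detections are reduced by cross-scale
  non-maximum suppression (strongest detection within
  $1.5\max(s_i,s_j)$ px wins), assigning each image structure a single
  scale, as scale-space detectors do. On sharp images fine scales win and
  the pipeline is exactly shift-covariant for integer translations; on
  blurred images the coarse octaves keep detection alive.
* **Continuous sampling.** Descriptor samples are box means evaluated at
  sub-pixel positions (bilinear interpolation of integer-centred box
  means), so descriptors vary continuously with the refined keypoint
  position instead of jumping at rounding boundaries.
* **Determinism.** There is no randomness at detection time; the only
  "random" objects are the frozen sampling patterns, generated from fixed
  seeds by a 32-bit multiplicative congruential generator independent of
  R's RNG. Two runs on the same image are bit-identical.
* **Octave anti-aliasing.** Octave pyramids apply a Gaussian pre-blur
  (sigma 1.4 px) before each 2× decimation, within the conventional range
  for pyramid construction, which keeps octave images insensitive to the
  sub-pixel phase of the content.

Descriptor bit lengths are asserted package-wide (orb 256, brisk 512,
akaze 486, ref 256) because the index's scale depends on them.

The pyramid structure of these implementations follows the published
algorithms, but they are not bit-compatible with any external library; in
particular keypoint *counts* are implementation-specific. Analyses in this
package therefore never depend on absolute keypoint counts, only on
matched-pair statistics.

## Conventional comparators

SSIM is implemented in-package as the standard windowed
luminance/contrast/structure product with $C_1=(K_1 R)^2$,
$C_2=(K_2 R)^2$; defaults: uniform 7×7 window, $K_1=0.01$, $K_2=0.03$,
data range $R$ from the bit depth (255 for 8-bit), population moments,
mean taken over all fully interior window positions (no padding). An
11-point Gaussian window (sigma 1.5) is available as an option. PSNR is
$10\log_{10}(R^2/\mathrm{MSE})$, reported as `Inf` for identical images.
All comparisons in the studies run on the same windowed 8-bit images the
feature backends see, so the three metrics always evaluate the same data.

## The synthetic phantom

All validation runs on a synthetic head-CT slice, generated in Hounsfield
units and stored like a CT acquisition (stored value = HU + 1024, 16-bit,
rescale intercept −1024, pixel spacing for a 250 mm field of view). The
default 512×512 phantom has:

* an **air** background at −1000 HU;
* a slightly elliptical **skull ring** (outer radius 0.45, inner 0.42 of
  the image side; bone at 1500 HU). Both boundary radii are modulated by a
  seeded harmonic profile (harmonics 8–64, amplitudes ∝ 1/k, standard
  deviation 1.1 % of the radius — bumps of a few pixels): real skulls are
  not smooth annuli, and these suture-like irregularities give the bone
  edge corner structure at full bone contrast, which is what survives
  heavy smoothing;
* a uniform **brain-like interior** at 40 HU carrying a smooth random
  **texture field** (Gaussian white noise smoothed with a 5 px Gaussian,
  5 HU standard deviation, fixed per phantom seed) standing in for
  parenchymal structure and reconstruction texture — the contrast
  continuum that gives feature detectors their working population of
  keypoints at every scale;
* 100 randomly placed, non-overlapping low-contrast **elliptical inserts**
  (semi-axes 2–12 px), each drawing its contrast as
  $\pm 15 \times 2^{u}$ HU with $u \sim U(-1,3)$ — from subtle 7.5 HU
  lesions to bright calcification-like foci — emulating the spread of
  tissue contrasts in a real slice.

Everything is deterministic given the spec's seed. The phantom is *not*
anatomically realistic: it has no gyral pattern, no beam-hardening or
streak artifacts, no correlated noise texture from a specific
reconstruction kernel, and its inserts are analytic ellipses. Passing
tests on this phantom therefore demonstrate the mechanics and the
directional behaviour of the index, not clinical performance on patient
data.

### Dose-dependent noise

Quantum noise is emulated as additive zero-mean white Gaussian noise with

$$\sigma(\mathrm{CTDI}) = \sigma_\mathrm{ref}
\sqrt{\mathrm{CTDI}_\mathrm{ref}/\mathrm{CTDI}},$$

the first-order behaviour of photon-count noise after reconstruction.
Defaults: $\mathrm{CTDI}_\mathrm{ref} = 89.1$ mGy,
$\sigma_\mathrm{ref} = 4$ HU — a typical measured noise level for
high-dose head CT. Noise is signal-independent and white (no kernel
colouring), values are rounded and clipped at the representable range
(physical saturation, not wrap-around), and a fixed seed makes each
realization reproducible. At the lowest simulated dose (2.7 mGy) the noise
reaches ≈ 23 HU, which after brain-windowing dominates the 8-bit image —
deliberately covering the regime where image quality fails outright.

### Windowing

Feature detection operates on 8-bit images. CT-like images are windowed
with a conventional brain display window (centre 40 HU, width 80 HU) by
default; the mapping is linear with round-half-up and clipping, and
monotone non-decreasing. 16-bit raster images without a CT rescale default
to min–max scaling.

## Degradation and transform series

* **Noise series**: CTDIvol ∈ {2.7, 5.5, 13.7, 21.9, 27.4, 35.6, 41.0,
  53.4, 59.4, 74.2} mGy against the 89.1 mGy reference.
* **Blur series**: Gaussian kernels $k$ = 3, 5, …, 21 with
  $\sigma = 0.3\,(k/2 - 1) + 0.8$ (so $k=3 \to 0.95$, $k=21 \to 3.65$).
  Note this is *not* the common library convention
  $0.3\,((k-1)/2 - 1) + 0.8$, which is exposed via
  `convention = "opencv"` for compatibility; the difference matters
  (0.95 vs 0.8 at $k=3$). Convolution is separable with reflective
  (edge-excluding) borders.
* **Affine series**: translations of 2–40 px (applied along x; positive
  dx moves content rightward), rotations of 1–45° and scalings 0.75–1.25
  about the geometric image centre $((w-1)/2,(h-1)/2)$, bilinear
  interpolation, exposed regions filled with 0 (air). Identity parameters
  reproduce the input bit-exactly and integer translations are lossless
  shifts.

## Study designs

**Validity** (`phantom_validity_study()`): the reference emulates the real
acquisition — the clean phantom plus reference-dose noise (89.1 mGy,
seed offset +998). Noise targets add dose-scaled noise to the *clean*
phantom (independent realizations per condition, seed offset +i), blur
targets smooth the 8-bit reference directly. Per condition and backend the
study records keypoint counts, matches, the index, SSIM and PSNR, then
summarizes Pearson correlations (index vs SSIM per backend and series;
PSNR vs SSIM per series) with the two-sided $t$-transform p-value at
$\alpha = 0.05$. Quality degradation should — and does — drive the index
up as SSIM falls: on the default phantom all four backends reach
$r \le -0.92$ on both series.

**Robustness** (`phantom_robustness_study()`): the affine battery runs
against the *noise-free* windowed phantom, so the series isolates
geometric effects from noise decorrelation. Alongside the correlation
table, a stability table reports the coefficient of variation (CV) of the
index and SSIM's relative range $(\max-\min)/\max$ per series and backend.
On the translation series SSIM falls by ≈ 45 % while the index stays
within a couple of bits of zero for all backends.

A degenerate case deserves note: because integer translation is exactly
lossless and the fine-scale pipeline is exactly shift-covariant, the index
under translation is *identically zero* for the single-scale backend and
nearly so (means of 0.05–0.3 bits out of 486/512) for the octave
backends, with only pyramid-phase jitter contributing for the multi-level
orb pyramid (mean ≈ 6 of 256 bits). A coefficient of variation divides by
these near-zero means and is therefore an ill-posed stability summary in
this regime — sub-bit absolute fluctuations can produce CVs of 1–3. The
stability table reports CV with the convention CV = 0 when the spread is
exactly zero, and readers should interpret it jointly with `pi_mean` and
`pi_sd`, which carry the physically meaningful (absolute) stability
statement. When the index is exactly constant across a series its
correlation with SSIM is undefined; the correlation table records `NA`
there — the extreme case of "no correlation" — rather than failing.

**Determinism**: one master seed governs the phantom, the reference
acquisition and every noise condition (all derived seeds stay below
$2^{31}$). Two study runs with the same configuration write byte-identical
CSV and JSON reports (numeric columns are serialized at full precision
with locale-independent formatting; reports carry no timestamps).

### Problem sizes

The studies default to the 512×512 phantom with the full condition grids
(20 validity conditions, 32 robustness conditions, four backends); a full
validity study completes in about a minute on a single core. Unit tests
exercise the same code paths on 192–256 px phantoms and reduced grids,
which preserve all qualitative behaviour.

## Input/output

Single-frame DICOM (uncompressed little-endian, unsigned MONOCHROME2),
PNG and TIFF (8/16-bit grayscale) are read into a common container that
carries bit depth, optional pixel spacing and the DICOM rescale
(slope/intercept), so Hounsfield units are available via `as_hu()`. The
DICOM reader is a minimal parser written for this package (no DICOM
library exists in this R stack); multi-frame, colour, signed and
compressed files are rejected with explicit unsupported-format errors
rather than misread. PNG/TIFF round trips are bit-exact.

## Known limitations

* The noise model is white and signal-independent; real CT noise is
  correlated by the reconstruction kernel and varies with attenuation.
* The phantom's realism limits are listed above; absolute index values on
  real scanner data will differ (the index has no normalized scale, a
  property inherent to the approach — values depend on backend, imaging
  system and protocol, so comparisons are only meaningful within a fixed
  configuration).
* Backends are in-package implementations of the published algorithm
  families, not bindings; keypoint counts and exact descriptor bits are
  not comparable with other implementations.
* Scale changes resample the image; the index's sensitivity to scaling
  mixes genuine feature change with interpolation effects, and the
  reduction/enlargement series should be read with that caveat.
* SSIM parameters (window, weighting) are conventions; different choices
  shift absolute SSIM values, though not the directional findings.
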