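---
title: "From RGB to reflectance spectra: model, calibration and evaluation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RGB to reflectance spectra: model, calibration and evaluation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model it
implements, the assumptions behind it, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the method left them open.

## 1. The model

### 1.1 Colorimetric kernel

All spectra live on a fixed grid, 380–780 nm at 1 nm (401 samples).
Tristimulus integration follows the CIE definition,

$$X = k \sum_\lambda S(\lambda)\,R(\lambda)\,\bar{x}(\lambda)\,\Delta\lambda,
\qquad k = \frac{100}{\sum_\lambda S(\lambda)\,\bar{y}(\lambda)\,\Delta\lambda},$$

with the analogous sums for $Y$ and $Z$. The brightness ratio $k$ forces a
perfect white reflector to $Y = 100$ under any illuminant, which anchors
the whole pipeline's scale. The integral is evaluated as a plain sum with
$\Delta\lambda = 1$ nm; at this tabulation the difference between
left-sum, trapezoid and fine-grid quadrature is below $10^{-6}$ relative
(the test suite checks agreement with a 0.1 nm trapezoid oracle to
$10^{-4}$). The CIE 1931 2° observer is bundled as a 401-row CSV,
spline-resampled once from the canonical 5 nm tabulation.

L\*a\*b\* conversion uses the standard piecewise cube-root companding
**relative to the session illuminant's whitepoint**, never a hard-coded
D65: the whitepoint is recomputed from $S(\lambda)$ via the same
integration with $R \equiv 1$. CIEDE2000 is implemented with unit
parametric factors ($k_L = k_C = k_H = 1$); the implementation is checked
against an independently sourced reference on 100 random Lab pairs to
$10^{-4}$ and against the canonical high-chroma blue pair that exercises
the rotation term.

### 1.2 Camera correction

Camera output is decoded from 8-bit sRGB with the IEC 61966-2-1 inverse
companding before the linear primaries matrix. The method itself is silent
on whether its cameras' JPEG gamma was decoded; we decode, on the argument
that the learned correction should absorb *residual, device-specific*
nonlinearity rather than re-learn the known sRGB curve. This is an
assumption, exposed by construction (the decode lives in one function) but
not configurable.

The correction model expands a camera color into twenty terms — every
monomial of $X, Y, Z$ up to total order three, in the fixed order
$[X^3\,Y^3\,Z^3\,X^2Y\,X^2Z\,Y^2Z\,XY^2\,XZ^2\,YZ^2\,XYZ\,X^2\,Y^2\,Z^2\,XY\,XZ\,YZ\,X\,Y\,Z\,\alpha]$
— and maps them to spectrometer coordinates with a $3\times 20$ matrix
fitted by Moore–Penrose pseudoinverse over the 24 patches. Three
modelling notes:

* **The dark constant $\alpha$ is fixed at 1.** The dark-current term
  enters the expansion as a constant; with $\alpha \equiv 1$ the matching
  column of $C$ *is* the learned dark level (an intercept). Estimating
  $\alpha$ separately would be an equivalent reparameterization with one
  more input to supply.
* **The gray-ramp polynomial analysis is diagnostic only.** Orders 1–3 are
  fitted to camera-vs-spectrometer brightness on the six neutral patches
  and their $R^2$ reported; a cubic fitting markedly better than the line
  is the evidence that justifies the cubic terms in the expansion. The
  correction itself always flows through $C$. With zero brightness
  variance, $R^2$ is reported as 0 by convention.
* **20 unknowns, 24 equations.** The fit is close to interpolation, which
  is intentional: the same 24 patches are both the calibration target and
  the evaluation target, and residual camera error — not regression bias —
  should dominate. The pseudoinverse truncates singular values below
  $10^{-10}\,\sigma_{\max}$ (configurable) as a rank guard; a
  rank-deficient expansion yields the minimum-norm solution and a warning.

### 1.3 Spectral basis and reconstruction

PCA of the 24 measured reflectances gives an orthonormal basis
(401 × 12 by default); a transformation matrix $M$ (12 × 7) maps the
chromatic cross-terms $[XYZ\,XY\,YZ\,XZ\,X\,Y\,Z]$ of a corrected color to
PCA scores, and the spectrum is $EV \cdot M \cdot V_{color}$.

**The PCA is uncentered by default.** This was a genuinely open design
point: standard PCA subtracts the mean, but the printed reconstruction has
no mean term and the 7-term color vector has no constant. The three pieces
are only mutually consistent *without* centering: reflectance→XYZ is a
homogeneous linear map, so uncentered scores are linear through the origin
in XYZ and an intercept-free regression can represent them. With centering,
flat (gray) spectra have scores affine in XYZ, the offset is unrepresentable,
and the gray ramp reconstructs poorly — the centered variant roughly
doubles the round-trip RMSE on synthetic checkers, and appending an
intercept column does not rescue it. Both modes are kept
(`fit_spectral_basis(..., center = TRUE)`, `fit_transformation_matrix(...,
intercept = TRUE)`); only the defaults changed.

Two asymmetries are implemented exactly as specified and deliberately not
"fixed": $M$ is fitted on *spectrometer* XYZ while reconstruction feeds
*corrected* XYZ (the two coincide up to residual correction error), and
$V_{color}$ has 7 terms while the correction expansion has 20.

Reconstructed reflectances may slightly overshoot $[0, 1]$; `clip_spectrum()`
clips to $[0, 1.2]$ **for display only** — RMSE is always computed on
unclipped values, because clipping would bias the error toward zero at the
range ends.

### 1.4 Lesion pipeline

Deep segmentation is out of scope by design: the value of a trained U-Net
lies in weights trained on private data, and the method's own framing is
that coarse segmentation suffices. The module therefore defines a mask
*interface* (any H×W binary mask, e.g. read from PNG) plus a classical
stand-in: threshold the shading-invariant redness ratio $(R-G)/(R+G)$ at
median + c·MAD over the image (c = 4 by default), then clean with a
morphological open/close (disc of 5 px). Its pre-threshold statistic,
squashed through a logistic, doubles as a probability map so the
cross-entropy / dice / IoU triple is computable. Empty∩empty masks score
dice = IoU = 1 (a perfect match of nothing).

Classification is **per image** (one sample per image), matching how such
datasets are counted, not per pixel. Features are per-region statistics of
per-pixel PCA scores: mean, SD and the 10/50/90th percentiles of each of
the 12 components (60 features; type-7 quantiles; SD of a single-pixel
region is 0). The classifier is a gradient-boosted tree ensemble
(multi-class softprob). The boosting defaults — 200 rounds, depth 4,
learning rate 0.1, 0.9 row/column subsampling, one thread, fixed seed —
are artifact decisions for a few hundred 60-dimensional samples, not claims
from the source method, which states none.

Cross-validation folds are **patient-grouped**: patients, not images, are
dealt into k folds (counts differing by ≤ 1, deterministic per seed), and
train/test patient disjointness is asserted on every fold of every run.
Metrics are macro one-vs-rest sensitivity, specificity, F1 and ROC-AUC
plus the pooled 4×4 confusion matrix. Whether published aggregates of this
kind are pooled-over-folds or mean-of-folds is generally ambiguous, so the
report carries both (`aggregate` = pooled, `mean_of_folds` alongside). A
fold missing a class warns and drops that class from that fold's mean;
pooled metrics are unaffected. ROC-AUC uses the trapezoid convention
(perfect scorer 1.0, constant scorer 0.5).

## 2. The synthetic-data generators

The study's clinical images are private, so every test input is generated:

* **Checker spectra**: three dominant broad Gaussian bands (centers
  450/550/650 nm, width 70 nm, uniform weights up to 0.45) over a baseline
  in [0.05, 0.30], plus up to three small detail bands (half-normal
  amplitude, SD 0.015) from a fixed 7-band dictionary; clipped to
  [0.02, 0.95]. Design intent: effective linear dimension ≤ 11 so the
  12-component claim is emulable, and — critically — variation dominated
  by few directions so a spectrum is *nearly determined by its color*.
  `detail_sd` is the metamerism dial: it sets the color-invisible variance
  and hence the floor of reconstruction error. Patches 19–24 are exactly
  flat neutrals at levels 0.90 … 0.05 (the gray ramp).
* **Illuminant**: a Planckian radiator at 5500 K (peak-normalized to 100)
  stands in for the unspecified studio source; a smooth broadband shape is
  the only property the method relies on. All results are conditioned on
  this choice.
* **Camera**: monotone polynomial channel nonlinearity on the XYZ/100
  scale (default test camera: $0.7t + 0.3t^3$), constant dark offset
  (1 Y-unit), zero-mean chrominance noise on X and Z (the color axes;
  noise is applied in XYZ, where the error taxonomy lives, not in RGB),
  then sRGB encoding with 8-bit quantization and gamut clipping.
* **Lesion images**: each patient draws a skin reflectance (melanin slope ×
  hemoglobin doublet depth at 542/577 nm); disease classes modify the
  carrier spectrum — deep doublet + long-wave absorption (MF), moderate
  doublet + raised red shelf (PsO, the scaly-plaque signature), mild
  doublet + blue-green dip (AD) — all scaled by a `separation` parameter
  so that 0 collapses every class onto normal skin. Images are an
  elliptical lesion over shaded, noise-textured skin, rendered through the
  camera model. Normal images have empty truth masks but carry an analysis
  ellipse so feature extraction is defined for all classes. Generators are
  bit-reproducible given (seed, spec).

What the generators do **not** emulate — and what passing tests therefore
do not show about real data: physical skin optics (no Kubelka–Munk or
photon transport), camera spectral sensitivities (errors are modeled in
XYZ, not through real channel responses), specular highlights, hair and
other artifacts, annotation noise in masks, and class imbalance across
body sites. The classification results on synthetic data demonstrate that
the *pipeline* recovers spectrally encoded class structure under grouped
validation; they are not a claim about clinical accuracy.

## 3. Numerical choices and degenerate inputs

* Pseudoinverse truncation $10^{-10}\sigma_{\max}$ for both $C$ and $M$
  (exposed as `pinv_tol`). The 20-term expansion spans ~8 orders of
  magnitude for colors on the Y∈[0,100] scale; the relative threshold
  keeps all informative directions while guarding exact rank deficiency.
* Argmax prediction ties break toward the first class in
  (normal, MF, PsO, AD) order, deterministically.
* Excluded cube pixels carry NA, never 0 — zero is a valid reflectance.
* Degenerate inputs fail loudly: all-zero illuminant, all-identical
  spectra, single-class training sets, empty feature regions, k exceeding
  the patient count, non-monotone camera nonlinearity.
* Fold shuffles, boosters and generators take explicit seeds; RNG state is
  restored after every seeded operation, so package calls never perturb the
  caller's random stream.

## 4. Problem sizes

The shipped tests and the acceptance checks run the checker pipeline at its
natural size (24 patches) and the classification pipeline at 20 patients ×
10 images of 64 × 64 px with 5-fold grouped CV — the scale at which the
class-recovery and null (label-permutation, zero-separation) behaviors are
stable and the whole suite still runs in well under a minute. The
generators accept larger sizes unchanged.

## 5. Known limitations

* A single correction matrix and basis per imaging session: no spatial
  flat-field or vignetting correction, no per-channel exposure estimation,
  no raw (Bayer) processing, no illuminant estimation from the image.
* Reconstruction is only as good as the color-determinedness of the target
  spectra; strong metamers are irrecoverable from a single RGB exposure by
  construction.
* The stand-in segmenter is a single-statistic thresholder: it will merge
  touching lesions, miss non-erythematous lesions, and is not a substitute
  scientific claim about segmentation accuracy on clinical images.
* 10° observer, alternative color-difference formulas and ICC profile
  handling are out of scope.
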