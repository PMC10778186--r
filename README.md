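# dermspectra

Reconstructs per-pixel visible reflectance spectra (380–780 nm at 1 nm, 401
bands) from ordinary RGB photographs, and uses the reconstructed spectra to
classify skin lesions. The intended users are researchers in spectral
imaging and computational dermatology who have a camera, a spectrometer and
a 24-patch color checker, and who want to move lesion analysis from the
3-channel color domain into the spectral domain — where visually confusable
conditions (early cutaneous T-cell lymphoma vs. psoriasis vs. atopic
dermatitis) are easier to tell apart.

## The method

**Cross-calibration.** A 24-patch checker (18 chromatic patches + 6 neutral
grays) is measured by both devices. Spectrometer reflectances R(λ) are
integrated against the CIE 1931 2° observer under the session illuminant
S(λ):

    X = k · Σ S(λ) R(λ) x̄(λ) Δλ,   k = 100 / Σ S(λ) ȳ(λ) Δλ

(and likewise Y, Z), so a perfect white maps to Y = 100. Camera sRGB values
are decoded (IEC 61966-2-1) to camera XYZ. The camera's residual errors —
a cubic nonlinearity (diagnosed on the gray ramp by polynomial regression
R²), dark current, and chrominance noise — are absorbed by a 3×20
correction matrix

    C = [XYZ_spectrometer] · pinv(V),   V = [X³ Y³ Z³ X²Y X²Z Y²Z XY² XZ² YZ² XYZ X² Y² Z² XY XZ YZ X Y Z α]ᵀ

fitted by Moore–Penrose pseudoinverse over the 24 patches; corrected colors
are C·V.

**Spectral reconstruction.** PCA of the 24 measured reflectances yields a
basis EV (12 components capture ≥ 99.9 % of variance). A transformation
matrix

    M = [score] · pinv(V_color),   V_color = [XYZ XY YZ XZ X Y Z]ᵀ

maps a single tristimulus color to the 12 PCA scores, so a full spectrum is
recovered from one corrected color: S = EV · M · V_color. Accuracy is
reported as spectral RMSE and as CIEDE2000 between the measured and
simulated colors.

**Lesion pipeline.** A pluggable mask interface (external masks, or a
built-in robust color-threshold segmenter scored by dice/IoU/cross-entropy)
delimits the lesion; every masked pixel is lifted to a spectrum; per-region
PCA-score statistics (mean, SD, 10/50/90th percentiles → 60 features) feed
a gradient-boosted tree classifier over four classes (normal, MF, PsO, AD),
evaluated with patient-grouped k-fold cross-validation (macro one-vs-rest
sensitivity, specificity, F1, ROC-AUC, confusion matrix) so no patient
leaks between training and testing.

Because clinical photographs are private, the package ships generators for
every input: smooth natural-object reflectances, a parametric camera
forward model (monotone polynomial nonlinearity, dark offset, chrominance
noise), synthetic checker scenes, and 4-class lesion image datasets with
masks and patient grouping.

## Worked example

```r
library(dermspectra)

# a camera with cubic nonlinearity, dark offset and chrominance noise
cam <- camera_model(gamma_poly = c(0.7, 0, 0.3), dark_offset = 1,
                    chroma_noise_sd = 0.25, seed = 0)
scene <- generate_checker_scene(seed = 0, cam = cam)

xyz_cam <- t(apply(scene$rgb, 1, function(p) unlist(srgb_to_xyz(p)[c("X","Y","Z")])))
calib <- fit_correction_matrix(xyz_cam, scene$xyz_true, gray_idx = scene$gray_idx)
calib
#> <calibration_model: 3x20 correction matrix, alpha = 1, fit on 24 patches>
#>   gray-ramp R^2 (orders 1-3): 0.98822 1.00000 1.00000

basis <- fit_transformation_matrix(fit_spectral_basis(scene$spectra, 12), scene$xyz_true)
evaluate_colorchecker(calib, basis, scene$rgb, scene$spectra, scene$illuminant)
#> <checker evaluation: 24 patches, mean RMSE 0.0192, mean dE2000 0.244>

# synthetic 4-class lesion dataset -> spectral features -> grouped 5-fold CV
ds <- generate_lesion_dataset(scene_spec(n_patients = 20, images_per_patient = 10,
                                         seed = 0), cam = cam)
samples <- build_sample_table(ds, calib, basis)
cv <- run_cross_validation(samples, k = 5, seed = 0)
cv
#> <cv_report: k = 5, pooled sensitivity 0.9881, specificity 0.9966, F1 0.9891, ROC-AUC 0.9995>
```

The gray-ramp R² sequence shows the cubic fitting the camera's
nonlinearity essentially perfectly (the diagnostic that motivates the cubic
terms in V). Mean RMSE 0.0192 means the reconstructed spectra deviate from
the measured ones by about 2 % reflectance per band; mean ΔE2000 0.24 is
well below a just-noticeable color difference. The cross-validation report
shows near-perfect recovery of the four classes at the generator's default
spectral separation — the confusion matrix (`cv$confusion`) misassigns only
2 of 200 images.

A command-line wrapper for the same steps lives in `inst/cli/dermspectra.R`
(subcommands `simulate`, `calibrate`, `segment`, `reconstruct`,
`classify-cv`).

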