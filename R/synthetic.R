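# Synthetic-data generators: reference Lab pairs for the checker
# evaluation, smooth natural-object reflectance spectra, a broadband
# illuminant, a parametric camera forward model (cubic nonlinearity, dark
# offset, chrominance noise), checker scenes, and 4-class lesion image
# datasets with masks and patient grouping. Everything is bit-reproducible
# given (seed, spec).

gauss_band <- function(center, width) exp(-((SPECTRUM_WL - center)^2) / (2 * width^2))

#' Measured/simulated L*a*b* pairs for the 24-patch checker evaluation
#'
#' The published checker evaluation: for each of the 24 patches, the
#' L*a*b* coordinates of the measured spectrum and of the spectrum
#' simulated by the reconstruction pipeline, with the reported CIEDE2000
#' difference (mean 0.28). Shipped as packaged data; used as the reference
#' input for the color-difference reproduction checks.
#'
#' @return Data frame with 24 rows: `patch_id`, `L_measured`, `a_measured`,
#'   `b_measured`, `L_simulated`, `a_simulated`, `b_simulated`,
#'   `de2000_reported`.
#' @export
colorchecker_lab_pairs <- function() {
  path <- system.file("extdata", "colorchecker24_lab_pairs.csv", package = "dermspectra")
  if (!nzchar(path)) stop("packaged checker Lab table not found", call. = FALSE)
  utils::read.csv(path)
}

#' Smooth broadband daylight-like illuminant
#'
#' A Planckian radiator at the given correlated color temperature,
#' normalized to peak 100 over 380-780 nm: a smooth, featureless broadband
#' source standing in for the unspecified studio illumination.
#'
#' @param cct_k Color temperature in kelvin (default 5500).
#' @return Illuminant spectrum.
#' @export
daylight_illuminant <- function(cct_k = 5500) {
  lam <- SPECTRUM_WL * 1e-9
  c2 <- 1.4388e-2
  b <- lam^-5 / (exp(c2 / (lam * cct_k)) - 1)
  spectrum(100 * b / max(b), kind = "illuminant")
}

#' Generate smooth natural-object reflectance spectra
#'
#' Each spectrum is a baseline plus a positive combination of broad
#' Gaussian bands: three dominant, strongly overlapping bands (centered in
#' the blue, green and red thirds of the grid) carry most of the
#' variation, and up to three narrow-amplitude detail bands from a fixed
#' seven-band dictionary add fine structure. Values are clipped to
#' \[0.02, 0.95\].
#'
#' This mirrors the statistics of natural-object reflectances measured on
#' calibration charts: smooth curves whose variation is dominated by a few
#' directions, so (a) any set of draws has effective linear dimension at
#' most 11 (3 + 7 bands + constant) and a 12-component PCA captures
#' essentially all variance, and (b) a spectrum is nearly determined by
#' its tristimulus color -- the regime in which color-to-spectrum
#' reconstruction is well posed. The `detail_sd` parameter controls the
#' metameric (color-invisible) variation and hence the floor of the
#' reconstruction error.
#'
#' @param n Number of spectra.
#' @param seed Integer seed (same seed, identical spectra).
#' @param baseline_range Uniform range of the flat baseline.
#' @param band_weight Amplitude scale of the three dominant bands.
#' @param detail_sd Amplitude scale (half-normal) of the detail bands.
#' @return List of `n` reflectance spectra.
#' @export
generate_reflectance_spectra <- function(n, seed = 0,
                                         baseline_range = c(0.05, 0.30),
                                         band_weight = 0.45,
                                         detail_sd = 0.015) {
  stopifnot(n >= 1)
  primary <- cbind(gauss_band(450, 70), gauss_band(550, 70), gauss_band(650, 70))
  centers <- seq(410, 770, length.out = 7)
  detail <- sapply(centers, gauss_band, width = 40)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      w_main <- stats::runif(3, 0, band_weight)
      nb <- sample(0:3, 1)
      v <- stats::runif(1, baseline_range[1], baseline_range[2]) +
        as.vector(primary %*% w_main)
      if (nb > 0) {
        bands <- sample(ncol(detail), nb)
        w_det <- abs(stats::rnorm(nb, 0, detail_sd))
        v <- v + as.vector(detail[, bands, drop = FALSE] %*% w_det)
      }
      spectrum(pmin(pmax(v, 0.02), 0.95), kind = "reflectance")
    })
  })
}

#' Parametric camera forward model
#'
#' The error sources the calibration is designed to invert: a monotone
#' per-channel polynomial nonlinearity (applied on the XYZ/100 scale), a
#' constant dark offset (dark current), and zero-mean chrominance noise on
#' the X and Z channels.
#'
#' @param gamma_poly Coefficients of the channel nonlinearity
#'   `f(t) = sum(gamma_poly[j] * t^j)` for `t = value / 100`; must be
#'   monotone increasing on \[0, 1\]. `c(1)` is the identity;
#'   `c(0.7, 0, 0.3)` is a cubic distortion.
#' @param dark_offset Additive constant in Y-units applied to all channels.
#' @param chroma_noise_sd Standard deviation of the noise on X and Z.
#' @param seed Integer seed used by [simulate_camera_response()].
#' @return A `camera_model`.
#' @export
camera_model <- function(gamma_poly = c(1), dark_offset = 0,
                         chroma_noise_sd = 0, seed = 0) {
  stopifnot(chroma_noise_sd >= 0, length(gamma_poly) >= 1)
  tt <- seq(0, 1, by = 0.01)
  f <- sapply(tt, function(t) sum(gamma_poly * t^seq_along(gamma_poly)))
  if (any(diff(f) < 0)) stop("gamma_poly must be monotone increasing on [0, 1]", call. = FALSE)
  structure(list(gamma_poly = gamma_poly, dark_offset = dark_offset,
                 chroma_noise_sd = chroma_noise_sd, seed = seed),
            class = "camera_model")
}

# Pure forward transform (uses the current RNG stream for the noise):
# n x 3 true XYZ -> n x 3 distorted camera XYZ.
camera_forward_xyz <- function(xyz_mat, cam) {
  t <- xyz_mat / 100
  out <- 0 * t
  for (j in seq_along(cam$gamma_poly)) out <- out + cam$gamma_poly[j] * t^j
  out <- 100 * out + cam$dark_offset
  if (cam$chroma_noise_sd > 0) {
    n <- nrow(out)
    eps <- matrix(stats::rnorm(2 * n), n, 2)
    out[, 1] <- out[, 1] + cam$chroma_noise_sd * eps[, 1]
    out[, 3] <- out[, 3] + cam$chroma_noise_sd * eps[, 2]
  }
  out
}

#' Simulate the camera's response to reflectance spectra
#'
#' True tristimulus values are computed by [spectrum_to_xyz()], the camera
#' model's nonlinearity, dark offset and chrominance noise are applied, and
#' the distorted XYZ is encoded to 8-bit sRGB. With an identity camera and
#' quantization disabled, the camera XYZ equals the true XYZ exactly. The
#' noise stream is seeded from `cam$seed`, so a fixed camera model gives
#' identical output across runs.
#'
#' @param R A reflectance spectrum or a list of them.
#' @param S Illuminant spectrum.
#' @param cam A `camera_model`.
#' @param cmf CMF set.
#' @param quantize Round the sRGB encoding to integers (default `TRUE`).
#' @return List with matrices `xyz_true`, `xyz_camera` (n x 3) and `rgb`
#'   (n x 3, 8-bit), plus the illuminant `whitepoint`.
#' @export
simulate_camera_response <- function(R, S, cam, cmf = load_cmf(), quantize = TRUE) {
  stopifnot(inherits(cam, "camera_model"))
  if (is_spectrum(R)) R <- list(R)
  conv <- lapply(R, spectrum_to_xyz, S = S, cmf = cmf)
  xyz_true <- do.call(rbind, lapply(conv, function(x) xyz_vec(x$xyz)))
  xyz_camera <- with_seed(cam$seed, camera_forward_xyz(xyz_true, cam))
  rgb <- xyz_to_srgb_matrix(xyz_camera, quantize = quantize)
  list(xyz_true = xyz_true, xyz_camera = xyz_camera, rgb = rgb,
       whitepoint = conv[[1]]$whitepoint)
}

#' Generate a synthetic 24-patch checker scene
#'
#' Structural emulation of a 24-patch chart: patches 1-18 are smooth
#' chromatic reflectances from [generate_reflectance_spectra()]; patches
#' 19-24 are spectrally flat neutrals at six descending reflectance levels
#' (the gray ramp the nonlinearity diagnostic uses). The scene does not
#' claim to match any commercial chart's reference spectra -- only the
#' chromatic + gray-ramp structure the algorithm depends on.
#'
#' @param seed Integer seed.
#' @param cam A `camera_model` used to render the camera colors.
#' @param cct_k Illuminant color temperature.
#' @return List with `spectra` (24), `illuminant`, `rgb` (24 x 3 8-bit
#'   camera colors), `xyz_true`, `xyz_camera`, and `gray_idx = 19:24`.
#' @export
generate_checker_scene <- function(seed = 0, cam = camera_model(), cct_k = 5500) {
  chromatic <- generate_reflectance_spectra(18, seed = seed)
  gray_levels <- c(0.90, 0.57, 0.36, 0.22, 0.12, 0.05)
  grays <- lapply(gray_levels, function(g) spectrum(rep(g, SPECTRUM_N)))
  spectra <- c(chromatic, grays)
  S <- daylight_illuminant(cct_k)
  resp <- simulate_camera_response(spectra, S, cam)
  list(spectra = spectra, illuminant = S, rgb = resp$rgb,
       xyz_true = resp$xyz_true, xyz_camera = resp$xyz_camera,
       gray_idx = 19:24)
}

# --- Skin and lesion spectra ------------------------------------------------

# Parametric skin reflectance: a red-rising base curve attenuated by a
# melanin-like short-wavelength slope and carved by the hemoglobin
# absorption doublet near 542/577 nm.
skin_reflectance <- function(melanin = 1, hemoglobin = 1) {
  wl <- SPECTRUM_WL
  base <- 0.18 + 0.50 * stats::plogis((wl - 580) / 50)
  mel <- exp(-0.10 * melanin * ((780 - wl) / 400)^1.5)
  hb <- 1 - hemoglobin * (0.30 * gauss_band(542, 13) + 0.24 * gauss_band(577, 11))
  spectrum(pmin(pmax(base * mel * hb, 0.02), 0.95), kind = "reflectance")
}

# Class-specific lesion reflectance derived from the carrier's skin
# spectrum. Signatures are band-depth modifications around the hemoglobin
# doublet plus class-specific broad-band changes, all scaled by the
# separation parameter: at separation 0 every class collapses onto normal
# skin (no signal), at 1 the classes are spectrally separable while
# remaining visually similar erythematous lesions.
lesion_reflectance <- function(skin, label, separation = 1) {
  v <- skin$values
  s <- separation
  mod <- switch(label,
    normal = rep(1, SPECTRUM_N),
    MF = 1 - s * (0.28 * gauss_band(542, 13) + 0.22 * gauss_band(577, 11) +
                    0.10 * gauss_band(690, 70)),
    PsO = 1 - s * (0.16 * gauss_band(542, 13) + 0.13 * gauss_band(577, 11)) +
      s * 0.10 * stats::plogis((SPECTRUM_WL - 620) / 40),
    AD = 1 - s * (0.09 * gauss_band(542, 13) + 0.07 * gauss_band(577, 11) +
                    0.06 * gauss_band(480, 50)),
    stop("unknown class label: ", label, call. = FALSE))
  spectrum(pmin(pmax(v * mod, 0.02), 0.95), kind = "reflectance")
}

#' Specification of a synthetic lesion-image dataset
#'
#' @param n_patients Number of patients.
#' @param images_per_patient Images per patient.
#' @param class_proportions Named proportions over
#'   `normal, MF, PsO, AD` (must sum to 1); image counts are the exact
#'   largest-remainder rounding of `proportions * n_images`.
#' @param image_size Square image side in pixels.
#' @param separation Class spectral-separation scale (0 = no class signal).
#' @param lesion_axes_frac Range of lesion ellipse semi-axes as a fraction
#'   of the image side.
#' @param seed Integer seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_patients = 20, images_per_patient = 10,
                       class_proportions = c(normal = 0.334, MF = 0.201,
                                             PsO = 0.254, AD = 0.211),
                       image_size = 64, separation = 1,
                       lesion_axes_frac = c(0.15, 0.30), seed = 0) {
  stopifnot(n_patients >= 1, images_per_patient >= 1, image_size >= 16,
            separation >= 0)
  if (!setequal(names(class_proportions), CLASS_LEVELS)) {
    stop("class_proportions must be named over: ",
         paste(CLASS_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-6) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  structure(list(n_patients = n_patients, images_per_patient = images_per_patient,
                 class_proportions = class_proportions[CLASS_LEVELS],
                 image_size = image_size, separation = separation,
                 lesion_axes_frac = lesion_axes_frac, seed = seed),
            class = "scene_spec")
}

# Exact largest-remainder apportionment of n into the class proportions.
apportion_classes <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  ((u / a)^2 + (v / b)^2 <= 1) + 0
}

#' Generate a synthetic 4-class lesion image dataset
#'
#' Desk-scale emulation of a clinical photograph collection: each patient
#' carries an individual skin spectrum (melanin/hemoglobin variation);
#' each image shows that skin with smooth shading and pixel noise and --
#' for the disease classes -- an elliptical lesion whose spectra carry the
#' class signature. Images are rendered to 8-bit RGB through the supplied
#' camera model. Ground-truth masks are the lesion ellipses (empty for
#' normal images); every image also carries an analysis region of interest
#' (the same ellipse; for normal images an ellipse placed on healthy skin)
#' so feature extraction is defined for all classes. Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec A `scene_spec`.
#' @param cam A `camera_model` used for rendering.
#' @param cct_k Illuminant color temperature.
#' @return List with `images` (one record per image: `image`, `mask`,
#'   `roi`, `label`, `patient_id`, `image_id`, `lesion_spectrum`,
#'   `skin_spectrum`), `samples` (data frame `image_id, patient_id, label`),
#'   and the shared `illuminant`.
#' @export
generate_lesion_dataset <- function(spec, cam = camera_model(), cct_k = 5500) {
  stopifnot(inherits(spec, "scene_spec"), inherits(cam, "camera_model"))
  n <- spec$n_patients * spec$images_per_patient
  counts <- apportion_classes(spec$class_proportions, n)
  S <- daylight_illuminant(cct_k)
  cmf <- load_cmf()
  size <- spec$image_size

  with_seed(spec$seed, {
    labels <- sample(rep(names(counts), counts))
    patient_id <- sprintf("P%03d", rep(seq_len(spec$n_patients),
                                       each = spec$images_per_patient))
    skin_by_patient <- replicate(spec$n_patients,
                                 skin_reflectance(melanin = stats::runif(1, 0.7, 1.4),
                                                  hemoglobin = stats::runif(1, 0.85, 1.15)),
                                 simplify = FALSE)
    images <- vector("list", n)
    for (i in seq_len(n)) {
      skin <- skin_by_patient[[rep(seq_len(spec$n_patients),
                                   each = spec$images_per_patient)[i]]]
      lab <- labels[i]
      lesion <- lesion_reflectance(skin, lab, separation = spec$separation)
      # image-level severity jitter on the lesion signature
      t_img <- stats::runif(1, 0.85, 1.0)
      lesion <- spectrum(skin$values + t_img * (lesion$values - skin$values),
                         kind = "reflectance")

      xyz_skin <- xyz_vec(spectrum_to_xyz(skin, S, cmf)$xyz)
      xyz_les <- xyz_vec(spectrum_to_xyz(lesion, S, cmf)$xyz)

      cx <- stats::runif(1, 0.35, 0.65) * size
      cy <- stats::runif(1, 0.35, 0.65) * size
      ax <- stats::runif(1, spec$lesion_axes_frac[1], spec$lesion_axes_frac[2]) * size
      bx <- stats::runif(1, spec$lesion_axes_frac[1], spec$lesion_axes_frac[2]) * size
      th <- stats::runif(1, 0, pi)
      roi_grid <- ellipse_mask(size, size, cx, cy, ax, bx, th)
      mask_grid <- if (lab == "normal") matrix(0, size, size) else roi_grid

      # smooth shading + per-pixel texture noise
      xs <- matrix(rep(seq_len(size), each = size), size, size) / size
      ys <- matrix(rep(seq_len(size), size), size, size) / size
      shading <- 1 - 0.12 * ((xs - 0.5)^2 + (ys - 0.5)^2) / 0.5 +
        0.02 * sin(2 * pi * xs) * cos(2 * pi * ys)
      shading <- shading * matrix(stats::rnorm(size^2, 1, 0.015), size, size)

      alpha <- as.vector(roi_grid) *
        pmin(pmax(stats::rnorm(size^2, 0.95, 0.04), 0), 1)
      if (lab == "normal") alpha <- alpha * 0
      xyz_px <- outer(1 - alpha, xyz_skin) + outer(alpha, xyz_les)
      xyz_px <- xyz_px * as.vector(shading)
      xyz_cam_px <- camera_forward_xyz(xyz_px, cam)
      rgb <- xyz_to_srgb_matrix(xyz_cam_px, quantize = TRUE)
      image <- array(rgb, dim = c(size, size, 3))

      images[[i]] <- list(image = image,
                          mask = lesion_mask(mask_grid),
                          roi = lesion_mask(roi_grid),
                          label = lab,
                          patient_id = patient_id[i],
                          image_id = sprintf("img%04d", i),
                          lesion_spectrum = lesion,
                          skin_spectrum = skin)
    }
    list(images = images,
         samples = data.frame(image_id = vapply(images, `[[`, character(1), "image_id"),
                              patient_id = patient_id,
                              label = labels,
                              stringsAsFactors = FALSE),
         illuminant = S)
  })
}

#' Build the classification sample table for a dataset
#'
#' Runs the full per-image spectral pipeline -- RGB to cube through the
#' calibration and basis, then spectral feature extraction over the
#' analysis region -- and assembles the `image_id, patient_id, label,
#' features` table consumed by [run_cross_validation()].
#'
#' @param dataset Output of [generate_lesion_dataset()].
#' @param calib A `calibration_model`.
#' @param basis A `spectral_basis` carrying M.
#' @return Data frame with identifiers, label and 60 feature columns.
#' @export
build_sample_table <- function(dataset, calib, basis) {
  feats <- lapply(dataset$images, function(rec) {
    cube <- image_to_cube(rec$image, calib, basis, mask = rec$roi)
    extract_features(cube, rec$roi, basis)
  })
  cbind(dataset$samples, as.data.frame(do.call(rbind, feats)))
}
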