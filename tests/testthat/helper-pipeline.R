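# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A camera with the distortions the calibration is designed to invert.
default_test_camera <- function(chroma_noise_sd = 0.25, seed = 0) {
  camera_model(gamma_poly = c(0.7, 0, 0.3), dark_offset = 1,
               chroma_noise_sd = chroma_noise_sd, seed = seed)
}

# Checker scene + fitted calibration and basis for a given camera.
calibrated_pipeline <- function(seed = 0, cam = camera_model()) {
  key <- paste0("pipe_", seed, "_", paste(cam$gamma_poly, collapse = "_"), "_",
                cam$dark_offset, "_", cam$chroma_noise_sd, "_", cam$seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  sc <- generate_checker_scene(seed, cam)
  xyz_cam <- t(sapply(seq_len(nrow(sc$rgb)),
                      function(i) unlist(srgb_to_xyz(sc$rgb[i, ])[c("X", "Y", "Z")])))
  calib <- fit_correction_matrix(xyz_cam, sc$xyz_true, gray_idx = sc$gray_idx)
  basis <- fit_transformation_matrix(fit_spectral_basis(sc$spectra, 12), sc$xyz_true)
  out <- list(scene = sc, calib = calib, basis = basis)
  .fixtures[[key]] <- out
  out
}

# Lesion dataset + feature table through the full spectral pipeline.
lesion_sample_table <- function(separation = 1, n_patients = 20,
                                images_per_patient = 10, seed = 0) {
  key <- paste0("tab_", separation, "_", n_patients, "_", images_per_patient, "_", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cam <- default_test_camera()
  pipe <- calibrated_pipeline(0, cam)
  ds <- generate_lesion_dataset(
    scene_spec(n_patients = n_patients, images_per_patient = images_per_patient,
               separation = separation, seed = seed), cam = cam)
  out <- list(dataset = ds, table = build_sample_table(ds, pipe$calib, pipe$basis),
              pipe = pipe)
  .fixtures[[key]] <- out
  out
}

mean_checker_rmse <- function(seed, cam) {
  pipe <- calibrated_pipeline(seed, cam)
  evaluate_colorchecker(pipe$calib, pipe$basis, pipe$scene$rgb,
                        pipe$scene$spectra, pipe$scene$illuminant)$mean_rmse
}
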