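test_that("basis fitting rejects degenerate input and honors exact low rank", {
  same <- replicate(24, spectrum(rep(0.5, 401)), simplify = FALSE)
  expect_error(fit_spectral_basis(same), "identical")
  expect_error(fit_spectral_basis(generate_reflectance_spectra(10, seed = 1)),
               "at least")

  # rank-2 family: centered PCA explains everything with 2 components
  set.seed(31)
  b1 <- exp(-((380:780 - 480)^2) / (2 * 60^2))
  b2 <- exp(-((380:780 - 650)^2) / (2 * 80^2))
  fam <- lapply(1:24, function(i) spectrum(0.1 + runif(1) * b1 + runif(1) * b2))
  fit <- fit_spectral_basis(fam, n_components = 3, center = TRUE)
  expect_equal(fit$explained_variance_cumulative[2], 1, tolerance = 1e-9)
})

test_that("basis components are orthonormal and variance fractions match an SVD oracle", {
  sp <- generate_reflectance_spectra(24, seed = 0)
  basis <- fit_spectral_basis(sp, 12)
  gram <- t(basis$EV) %*% basis$EV
  expect_lt(max(abs(gram - diag(12))), 1e-8)
  expect_true(all(diff(basis$explained_variance_cumulative) >= 0))
  expect_lte(basis$explained_variance_cumulative[12], 1 + 1e-12)
  # independent oracle: eigenvalues of the Gram matrix
  X <- do.call(rbind, lapply(sp, `[[`, "values"))
  ev <- eigen(X %*% t(X), symmetric = TRUE, only.values = TRUE)$values
  oracle <- cumsum(ev)[12] / sum(ev)
  expect_equal(basis$explained_variance_cumulative[12], oracle, tolerance = 1e-10)
  expect_gte(basis$explained_variance_cumulative[12], 0.999)
})

test_that("keeping all components reconstructs training spectra exactly", {
  sp <- generate_reflectance_spectra(24, seed = 2)
  X <- do.call(rbind, lapply(sp, `[[`, "values"))
  full <- fit_spectral_basis(sp, n_components = 23, center = TRUE)
  recon <- sweep(full$scores %*% t(full$EV), 2, full$mean_spectrum, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)

  # truncation error is nonincreasing in component count
  errs <- vapply(c(2, 4, 8, 12, 16), function(k) {
    b <- fit_spectral_basis(sp, n_components = k)
    mean(sqrt(rowMeans((b$scores %*% t(b$EV) - X)^2)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("select_n_components finds the variance-threshold count", {
  sp <- generate_reflectance_spectra(24, seed = 0)
  k <- select_n_components(sp, threshold = 0.9999)
  expect_lte(k, 12)
  cum <- fit_spectral_basis(sp, 12)$explained_variance_cumulative
  expect_gte(cum[k], 0.9999)
  if (k > 1) expect_lt(cum[k - 1], 0.9999)
})

test_that("transformation matrix recovers a planted score-color relation", {
  set.seed(33)
  sp <- generate_reflectance_spectra(24, seed = 4)
  basis <- fit_spectral_basis(sp, 12)
  xyz <- matrix(runif(72, 5, 95), 24, 3)
  M_true <- matrix(rnorm(12 * 7, 0, 0.05), 12, 7)
  basis$scores <- t(M_true %*% dermspectra:::vcolor_matrix(xyz))
  fitted <- fit_transformation_matrix(basis, xyz)
  pred <- t(fitted$M %*% dermspectra:::vcolor_matrix(xyz))
  expect_lt(max(abs(pred - basis$scores)), 1e-8)

  basis$scores[] <- 0
  expect_lt(max(abs(fit_transformation_matrix(basis, xyz)$M)), 1e-12)
  expect_error(fit_transformation_matrix(basis, xyz[1:10, ]), "mismatch")
})

test_that("duplicated color columns still yield consistent minimum-norm predictions", {
  set.seed(34)
  sp <- generate_reflectance_spectra(24, seed = 5)
  basis <- fit_spectral_basis(sp, 12)
  xyz <- matrix(runif(72, 5, 95), 24, 3)
  xyz[2, ] <- xyz[1, ]   # duplicated patch
  fitted <- fit_transformation_matrix(basis, xyz)
  pred <- t(fitted$M %*% dermspectra:::vcolor_matrix(xyz))
  expect_equal(pred[1, ], pred[2, ], tolerance = 1e-10)
})

test_that("reconstruction contracts hold (provenance, M, centered mean fallback)", {
  sp <- generate_reflectance_spectra(24, seed = 6)
  basis <- fit_spectral_basis(sp, 12, center = TRUE)
  expect_error(reconstruct_spectrum(basis, xyz_color(10, 10, 10, "corrected")),
               "incomplete")
  basis <- fit_transformation_matrix(basis, matrix(runif(72, 5, 95), 24, 3))
  expect_error(reconstruct_spectrum(basis, xyz_color(10, 10, 10, "camera")),
               "corrected")
  # M = 0 collapses every reconstruction onto the mean spectrum
  basis$M[] <- 0
  rec <- reconstruct_spectrum(basis, xyz_color(33, 44, 55, "corrected"))
  expect_equal(rec$values, basis$mean_spectrum, tolerance = 1e-12)
  expect_identical(rec$kind, "reconstructed")
})

test_that("a family with exactly color-linear scores is recovered exactly", {
  set.seed(35)
  donor <- fit_spectral_basis(generate_reflectance_spectra(24, seed = 7), 12)
  xyz <- matrix(runif(72, 10, 90), 24, 3)
  M_true <- matrix(rnorm(12 * 7, 0, 1e-3), 12, 7)
  X <- t(donor$EV %*% (M_true %*% dermspectra:::vcolor_matrix(xyz)))
  fam <- lapply(seq_len(24), function(i) spectrum(X[i, ], kind = "reconstructed"))
  basis <- fit_transformation_matrix(fit_spectral_basis(fam, 12), xyz)
  rec <- dermspectra:::reconstruct_matrix(basis, xyz)
  expect_lt(max(abs(rec - X)), 1e-6)
})

test_that("checker round-trip report has coherent means and reaches the expected accuracy", {
  pipe <- calibrated_pipeline(0, default_test_camera(chroma_noise_sd = 0))
  rep <- evaluate_colorchecker(pipe$calib, pipe$basis, pipe$scene$rgb,
                               pipe$scene$spectra, pipe$scene$illuminant)
  expect_length(rep$per_patch_rmse, 24)
  expect_equal(rep$mean_rmse, mean(rep$per_patch_rmse))
  expect_equal(rep$mean_de2000, mean(rep$per_patch_de2000))
  expect_true(all(rep$per_patch_rmse >= 0) && all(rep$per_patch_de2000 >= 0))
  expect_lte(rep$mean_rmse, 0.05)
  expect_lte(rep$mean_de2000, 1.0)
})

test_that("feeding measured colors on both sides leaves only regression/truncation error", {
  sc <- generate_checker_scene(1, camera_model())
  basis <- fit_transformation_matrix(fit_spectral_basis(sc$spectra, 12), sc$xyz_true)
  rec <- dermspectra:::reconstruct_matrix(basis, sc$xyz_true)
  meas <- do.call(rbind, lapply(sc$spectra, `[[`, "values"))
  direct_rmse <- sqrt(rowMeans((rec - meas)^2))
  # the color-term regression cannot beat the PCA truncation floor
  trunc <- meas %*% basis$EV %*% t(basis$EV)
  floor_rmse <- sqrt(rowMeans((trunc - meas)^2))
  expect_true(all(direct_rmse >= floor_rmse - 1e-10))
  expect_lte(mean(direct_rmse), 0.06)
})

test_that("spectral basis JSON round-trips including M", {
  sp <- generate_reflectance_spectra(24, seed = 8)
  basis <- fit_transformation_matrix(fit_spectral_basis(sp, 12),
                                     matrix(runif(72, 5, 95), 24, 3))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_basis_json(basis, tmp)
  back <- read_basis_json(tmp)
  expect_equal(back$EV, basis$EV, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$M, basis$M, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$center, basis$center)
  x <- xyz_color(40, 50, 60, "corrected")
  expect_equal(reconstruct_spectrum(back, x)$values,
               reconstruct_spectrum(basis, x)$values, tolerance = 1e-10)
})
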