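# PCA basis of the checker reflectance spectra, the transformation matrix M
# from color polynomial terms to PCA scores, spectrum reconstruction, and
# the checker round-trip evaluation report.

VCOLOR_TERMS <- c("XYZ", "XY", "YZ", "XZ", "X", "Y", "Z")

# Chromatic cross-term vector: 7 terms [XYZ XY YZ XZ X Y Z], optionally an
# appended constant. n x 3 XYZ matrix -> (7|8) x n.
vcolor_matrix <- function(xyz_mat, intercept = FALSE) {
  X <- xyz_mat[, 1]; Y <- xyz_mat[, 2]; Z <- xyz_mat[, 3]
  V <- rbind(X * Y * Z, X * Y, Y * Z, X * Z, X, Y, Z)
  rownames(V) <- VCOLOR_TERMS
  if (intercept) V <- rbind(V, const = rep(1, ncol(V)))
  V
}

#' Fit a PCA basis to a set of reflectance spectra
#'
#' Principal component analysis of the training reflectance spectra
#' (typically the 24 checker patches). Components are ordered by
#' decreasing captured variance; the default 12 components capture
#' essentially all variance of natural-object reflectances measured on
#' such charts.
#'
#' By default the PCA is *uncentered* (`center = FALSE`): reflectance to
#' tristimulus is a homogeneous linear map, so uncentered scores are
#' linear through the origin in XYZ and consistent with the
#' intercept-free color-term regression and the mean-free reconstruction
#' -- empirically about half the round-trip error of the centered
#' variant on checker-like spectra. With `center = TRUE` the mean
#' spectrum is subtracted first and added back at reconstruction.
#'
#' @param spectra List of at least `n_components + 1` reflectance spectra.
#' @param n_components Number of principal components kept (default 12).
#' @param center Mean-center before PCA (default `FALSE`; see above).
#' @return A `spectral_basis`: `mean_spectrum` (401), `EV` (401 x
#'   n_components, orthonormal columns), `scores` (n x n_components),
#'   `explained_variance_cumulative`, `center`, and `M = NULL` until
#'   [fit_transformation_matrix()] is called.
#' @export
fit_spectral_basis <- function(spectra, n_components = 12, center = FALSE) {
  mat <- spectra_matrix(spectra)                     # n x 401
  n <- nrow(mat)
  if (n < n_components + 1) {
    stop("need at least n_components + 1 = ", n_components + 1,
         " spectra, got ", n, call. = FALSE)
  }
  if (max(apply(mat, 2, stats::var)) <= .Machine$double.eps) {
    stop("spectra are all identical: zero variance, no basis can be fitted", call. = FALSE)
  }
  mu <- if (center) colMeans(mat) else rep(0, ncol(mat))
  Xc <- sweep(mat, 2, mu)
  sv <- svd(Xc)
  EV <- sv$v[, seq_len(n_components), drop = FALSE]          # 401 x k
  scores <- Xc %*% EV                                        # n x k
  ev_all <- sv$d^2 / sum(sv$d^2)
  cum <- cumsum(ev_all)[seq_len(n_components)]
  structure(list(mean_spectrum = mu, EV = EV, scores = scores,
                 explained_variance_cumulative = cum,
                 n_components = n_components, center = center, M = NULL,
                 vcolor_intercept = FALSE),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis: %d components, %.5f%% variance, M %s>\n",
              x$n_components, 100 * utils::tail(x$explained_variance_cumulative, 1),
              if (is.null(x$M)) "not fitted" else "fitted"))
  invisible(x)
}

#' Choose the component count reaching a variance threshold
#'
#' Variance-threshold alternative to a fixed component count: the smallest
#' number of components whose cumulative explained variance reaches
#' `threshold`.
#'
#' @param spectra List of reflectance spectra.
#' @param threshold Cumulative explained-variance target (default 0.9999).
#' @param center Passed to [fit_spectral_basis()].
#' @return Integer component count.
#' @export
select_n_components <- function(spectra, threshold = 0.9999, center = FALSE) {
  mat <- spectra_matrix(spectra)
  mu <- if (center) colMeans(mat) else rep(0, ncol(mat))
  sv <- svd(sweep(mat, 2, mu))
  cum <- cumsum(sv$d^2) / sum(sv$d^2)
  as.integer(which(cum >= threshold)[1])
}

#' Fit the transformation matrix M from color terms to PCA scores
#'
#' Least-squares map `M = t(scores) %*% pinv(V_color)` where `V_color` is
#' the 7-term chromatic cross-term matrix `[XYZ XY YZ XZ X Y Z]` built from
#' the spectrometer tristimulus values of the training patches. M bridges
#' the measurement gap between a single tristimulus color and the
#' 12-dimensional spectral score space.
#'
#' @param basis A `spectral_basis` whose training scores align row-for-row
#'   with `xyz_spectrometer`.
#' @param xyz_spectrometer List of `xyz_color` (spectrometer provenance) or
#'   n x 3 matrix, one row per training patch.
#' @param intercept Append a constant 8th term to `V_color` (default
#'   `FALSE`, matching the 7-term definition).
#' @param pinv_tol Relative singular-value truncation threshold.
#' @return The basis with `M` (n_components x 7, or x 8 with intercept) set.
#' @export
fit_transformation_matrix <- function(basis, xyz_spectrometer, intercept = FALSE,
                                      pinv_tol = 1e-10) {
  stopifnot(inherits(basis, "spectral_basis"))
  ref <- as_xyz_matrix(xyz_spectrometer, "spectrometer")
  if (nrow(ref) != nrow(basis$scores)) {
    stop("patch count mismatch: basis has ", nrow(basis$scores),
         " training scores, got ", nrow(ref), " XYZ entries", call. = FALSE)
  }
  V <- vcolor_matrix(ref, intercept = intercept)      # 7 x n
  basis$M <- t(basis$scores) %*% pracma::pinv(V, tol = pinv_tol)  # tol relative to sigma_max
  basis$vcolor_intercept <- intercept
  basis
}

#' Reconstruct a full reflectance spectrum from one corrected color
#'
#' The reconstructed hyperspectrum is
#' `mean_spectrum + EV %*% (M %*% V_color(xyz))`, i.e. the color's
#' chromatic cross-terms are mapped to PCA scores by M and expanded on the
#' spectral basis. The mean add-back matches the mean-centered PCA used in
#' fitting (with `center = FALSE` bases there is no mean term).
#'
#' @param basis A `spectral_basis` carrying M.
#' @param xyz_corrected An `xyz_color` with corrected provenance (output of
#'   [apply_correction()]).
#' @return A spectrum of kind `"reconstructed"` (unclipped; see
#'   [clip_spectrum()] for display).
#' @export
reconstruct_spectrum <- function(basis, xyz_corrected) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (is.null(basis$M)) {
    stop("basis is incomplete: fit_transformation_matrix() has not been run", call. = FALSE)
  }
  if (!inherits(xyz_corrected, "xyz_color") || xyz_corrected$provenance != "corrected") {
    stop("`xyz_corrected` must be an xyz_color with corrected provenance", call. = FALSE)
  }
  v <- reconstruct_matrix(basis, matrix(xyz_vec(xyz_corrected), nrow = 1))
  spectrum(v[1, ], kind = "reconstructed")
}

# Vectorized reconstruction: n x 3 corrected XYZ -> n x 401 spectra matrix.
reconstruct_matrix <- function(basis, xyz_mat) {
  V <- vcolor_matrix(xyz_mat, intercept = basis$vcolor_intercept)
  out <- t(basis$EV %*% (basis$M %*% V))              # n x 401
  sweep(out, 2, basis$mean_spectrum, `+`)
}

#' Round-trip evaluation on a 24-patch checker
#'
#' For each patch: decode the camera color, apply the correction matrix,
#' reconstruct the spectrum, and compare with the measured spectrum by RMSE
#' (on unclipped values) and by CIEDE2000 between the L*a*b* renderings of
#' both spectra under the session illuminant.
#'
#' @param calib A `calibration_model`.
#' @param basis A `spectral_basis` carrying M.
#' @param checker_rgb 24 x 3 matrix of 8-bit camera colors, patch order
#'   matching `checker_spectra`.
#' @param checker_spectra List of 24 measured reflectance spectra.
#' @param S Session illuminant spectrum.
#' @param cmf CMF set (default the bundled CIE 1931 2-degree observer).
#' @return A `checker_eval_report`: `per_patch_rmse`, `mean_rmse`,
#'   `per_patch_de2000`, `mean_de2000`, and `lab_pairs` (24 rows of measured
#'   and simulated L*a*b*).
#' @export
evaluate_colorchecker <- function(calib, basis, checker_rgb, checker_spectra, S,
                                  cmf = load_cmf()) {
  stopifnot(inherits(calib, "calibration_model"), inherits(basis, "spectral_basis"))
  n <- length(checker_spectra)
  checker_rgb <- as.matrix(checker_rgb)
  if (nrow(checker_rgb) != n) {
    stop("checker_rgb rows (", nrow(checker_rgb), ") != number of spectra (", n, ")",
         call. = FALSE)
  }
  wp <- illuminant_whitepoint(S, cmf)
  rmse <- de <- numeric(n)
  lab_pairs <- data.frame(patch = seq_len(n),
                          L_measured = NA_real_, a_measured = NA_real_, b_measured = NA_real_,
                          L_simulated = NA_real_, a_simulated = NA_real_, b_simulated = NA_real_)
  for (i in seq_len(n)) {
    cam <- srgb_to_xyz(checker_rgb[i, ])
    corrected <- apply_correction(calib, cam)
    recon <- reconstruct_spectrum(basis, corrected)
    rmse[i] <- rmse_spectra(recon, checker_spectra[[i]])
    lab_m <- xyz_to_lab(spectrum_to_xyz(checker_spectra[[i]], S, cmf)$xyz, wp)
    lab_s <- xyz_to_lab(spectrum_to_xyz(recon, S, cmf)$xyz, wp)
    de[i] <- ciede2000(lab_m, lab_s)
    lab_pairs[i, 2:7] <- c(lab_m$L, lab_m$a, lab_m$b, lab_s$L, lab_s$a, lab_s$b)
  }
  structure(list(per_patch_rmse = rmse, mean_rmse = mean(rmse),
                 per_patch_de2000 = de, mean_de2000 = mean(de),
                 lab_pairs = lab_pairs),
            class = "checker_eval_report")
}

#' @export
print.checker_eval_report <- function(x, ...) {
  cat(sprintf("<checker evaluation: %d patches, mean RMSE %.4f, mean dE2000 %.3f>\n",
              length(x$per_patch_rmse), x$mean_rmse, x$mean_de2000))
  invisible(x)
}

#' Serialize a spectral basis to JSON
#' @param basis A `spectral_basis`.
#' @param path Output JSON path.
#' @export
write_basis_json <- function(basis, path) {
  stopifnot(inherits(basis, "spectral_basis"))
  obj <- list(mean_spectrum = basis$mean_spectrum,
              EV = as.vector(t(basis$EV)), ev_dim = dim(basis$EV),
              scores = as.vector(t(basis$scores)), scores_dim = dim(basis$scores),
              explained_variance_cumulative = basis$explained_variance_cumulative,
              n_components = basis$n_components, center = basis$center,
              vcolor_intercept = basis$vcolor_intercept,
              M = if (is.null(basis$M)) NULL else as.vector(t(basis$M)),
              m_dim = if (is.null(basis$M)) NULL else dim(basis$M))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a spectral basis from JSON
#' @param path JSON path written by [write_basis_json()].
#' @return A `spectral_basis`.
#' @export
read_basis_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_spectrum = o$mean_spectrum,
                 EV = matrix(o$EV, nrow = o$ev_dim[1], byrow = TRUE),
                 scores = matrix(o$scores, nrow = o$scores_dim[1], byrow = TRUE),
                 explained_variance_cumulative = o$explained_variance_cumulative,
                 n_components = o$n_components, center = o$center,
                 vcolor_intercept = isTRUE(o$vcolor_intercept),
                 M = if (is.null(o$M)) NULL else matrix(o$M, nrow = o$m_dim[1], byrow = TRUE)),
            class = "spectral_basis")
}
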