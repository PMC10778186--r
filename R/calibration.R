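# Camera error-correction model: gray-ramp nonlinearity diagnostics, the
# 20-term polynomial variable vector, and the 3x20 correction matrix C
# fitted by Moore-Penrose pseudoinverse.

# Deterministic order of the 20 polynomial terms.
VARIABLE_TERMS <- c("X3", "Y3", "Z3", "X2Y", "X2Z", "Y2Z", "XY2", "XZ2", "YZ2",
                    "XYZ", "X2", "Y2", "Z2", "XY", "XZ", "YZ", "X", "Y", "Z", "alpha")

#' Expand a tristimulus value into the 20-term polynomial variable vector
#'
#' The camera correction operates on a cubic polynomial expansion of the
#' camera XYZ: all monomials up to order three in X, Y, Z (cubes, mixed
#' cubics, squares, pairwise products and the linear terms) plus the dark
#' constant `alpha`. The term order is fixed:
#' `X^3 Y^3 Z^3 X^2Y X^2Z Y^2Z XY^2 XZ^2 YZ^2 XYZ X^2 Y^2 Z^2 XY XZ YZ X Y Z alpha`.
#'
#' @param xyz An `xyz_color` or numeric `(X, Y, Z)` triple.
#' @param alpha Dark constant appended as the 20th term (default 1, making
#'   the matching column of the correction matrix a learned intercept).
#' @return Named numeric vector of length 20.
#' @examples
#' expand_variable_vector(c(2, 1, 0))
#' @export
expand_variable_vector <- function(xyz, alpha = 1) {
  v <- if (inherits(xyz, "xyz_color")) xyz_vec(xyz) else as.numeric(xyz)
  if (length(v) != 3 || any(!is.finite(v))) {
    stop("`xyz` must be a finite tristimulus triple", call. = FALSE)
  }
  X <- v[1]; Y <- v[2]; Z <- v[3]
  out <- c(X^3, Y^3, Z^3, X^2 * Y, X^2 * Z, Y^2 * Z, X * Y^2, X * Z^2, Y * Z^2,
           X * Y * Z, X^2, Y^2, Z^2, X * Y, X * Z, Y * Z, X, Y, Z, alpha)
  names(out) <- VARIABLE_TERMS
  out
}

# Vectorized expansion: n x 3 XYZ matrix -> 20 x n variable matrix.
variable_matrix <- function(xyz_mat, alpha = 1) {
  X <- xyz_mat[, 1]; Y <- xyz_mat[, 2]; Z <- xyz_mat[, 3]
  V <- rbind(X^3, Y^3, Z^3, X^2 * Y, X^2 * Z, Y^2 * Z, X * Y^2, X * Z^2, Y * Z^2,
             X * Y * Z, X^2, Y^2, Z^2, X * Y, X * Z, Y * Z, X, Y, Z,
             rep(alpha, length(X)))
  rownames(V) <- VARIABLE_TERMS
  V
}

#' Polynomial nonlinearity analysis on the gray ramp
#'
#' Regresses spectrometer brightness (Y) on camera brightness for the
#' neutral gray patches (patches 19-24 of a standard 24-patch checker) with
#' ordinary least-squares polynomials of order 1, 2 and 3, reporting the
#' coefficient of determination of each. A cubic fitting markedly better
#' than the linear fit is the diagnostic that justifies the cubic terms in
#' the correction matrix; the correction itself always flows through
#' [fit_correction_matrix()].
#'
#' @param y_camera,y_spectrometer Paired positive brightness values for the
#'   gray patches (at least 4 levels, so the cubic is determined).
#' @return List with one entry per order (`order1`..`order3`), each holding
#'   `coefficients` (increasing powers) and `r_squared`, plus `best_order`.
#'   With constant `y_spectrometer` the total variance is zero and R^2 is
#'   reported as 0 for all orders (documented convention).
#' @export
fit_nonlinearity <- function(y_camera, y_spectrometer) {
  y_camera <- as.numeric(y_camera); y_spectrometer <- as.numeric(y_spectrometer)
  if (length(y_camera) != length(y_spectrometer)) {
    stop("gray-patch sequences must have equal length", call. = FALSE)
  }
  if (length(y_camera) < 4) {
    stop("need at least 4 gray levels (cubic fit underdetermined)", call. = FALSE)
  }
  if (any(y_camera <= 0) || any(y_spectrometer <= 0)) {
    stop("gray-patch brightness values must be positive", call. = FALSE)
  }
  sst <- sum((y_spectrometer - mean(y_spectrometer))^2)
  fits <- lapply(1:3, function(d) {
    fit <- stats::lm(y_spectrometer ~ stats::poly(y_camera, degree = d, raw = TRUE))
    r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
    list(coefficients = unname(stats::coef(fit)), r_squared = r2)
  })
  names(fits) <- paste0("order", 1:3)
  fits$best_order <- unname(which.max(vapply(fits[1:3], `[[`, numeric(1), "r_squared")))
  fits
}

#' Fit the 3x20 camera correction matrix
#'
#' Solves `C = XYZ_spectrometer %*% pinv(V)` where `V` is the 20 x n matrix
#' of polynomial variable vectors expanded from the camera XYZ of the
#' checker patches and `XYZ_spectrometer` is the matching 3 x n matrix of
#' reference tristimulus values. The Moore-Penrose pseudoinverse yields the
#' minimum-norm least-squares solution; singular values below
#' `pinv_tol * sigma_max` are truncated as a numerical rank guard.
#'
#' @param xyz_camera List of `xyz_color` with camera provenance (or n x 3
#'   matrix), one per patch; at least 20 patches.
#' @param xyz_spectrometer Matching list of `xyz_color` with spectrometer
#'   provenance (or n x 3 matrix).
#' @param alpha Dark constant fed to the variable expansion (default 1).
#' @param gray_idx Indices (1-based) of the neutral gray-ramp patches used
#'   for the nonlinearity diagnostic; `NULL` skips the diagnostic.
#' @param pinv_tol Relative singular-value truncation threshold.
#' @return A `calibration_model`: list with the 3 x 20 matrix `C`, `alpha`,
#'   `nonlinearity_report`, `n_patches` and `pinv_tol`.
#' @export
fit_correction_matrix <- function(xyz_camera, xyz_spectrometer, alpha = 1,
                                  gray_idx = 19:24, pinv_tol = 1e-10) {
  cam <- as_xyz_matrix(xyz_camera, "camera")
  ref <- as_xyz_matrix(xyz_spectrometer, "spectrometer")
  if (nrow(cam) != nrow(ref)) {
    stop("camera and spectrometer patch counts differ", call. = FALSE)
  }
  n <- nrow(cam)
  if (n < 20) stop("need at least 20 patches to determine the 20-term model", call. = FALSE)

  V <- variable_matrix(cam, alpha = alpha)        # 20 x n
  if (qr(V)$rank < 20) {
    warning("variable matrix is rank-deficient; pseudoinverse returns the minimum-norm solution")
  }
  C <- t(ref) %*% pracma::pinv(V, tol = pinv_tol)   # 3 x 20 (tol is relative to sigma_max)

  report <- NULL
  if (!is.null(gray_idx)) {
    gray_idx <- as.integer(gray_idx)
    if (any(gray_idx < 1) || any(gray_idx > n)) {
      stop("gray_idx out of range for ", n, " patches", call. = FALSE)
    }
    report <- fit_nonlinearity(cam[gray_idx, 2], ref[gray_idx, 2])
  }
  structure(list(C = C, alpha = alpha, nonlinearity_report = report,
                 n_patches = n, pinv_tol = pinv_tol),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model: 3x20 correction matrix, alpha = %g, fit on %d patches>\n",
              x$alpha, x$n_patches))
  if (!is.null(x$nonlinearity_report)) {
    r2 <- vapply(x$nonlinearity_report[1:3], `[[`, numeric(1), "r_squared")
    cat(sprintf("  gray-ramp R^2 (orders 1-3): %.5f %.5f %.5f\n", r2[1], r2[2], r2[3]))
  }
  invisible(x)
}

# Accept a list of xyz_color (checking provenance) or a bare n x 3 matrix.
as_xyz_matrix <- function(x, provenance = NULL) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop("XYZ matrix must have 3 columns", call. = FALSE)
    return(x)
  }
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "xyz_color")) {
    if (!is.null(provenance)) {
      got <- vapply(x, `[[`, character(1), "provenance")
      if (any(got != provenance)) {
        stop("expected ", provenance, " provenance, got: ",
             paste(unique(got), collapse = ", "), call. = FALSE)
      }
    }
    return(do.call(rbind, lapply(x, xyz_vec)))
  }
  stop("expected a list of xyz_color or an n x 3 matrix", call. = FALSE)
}

#' Apply the camera correction to a tristimulus value
#'
#' Corrected XYZ is `C %*% V` with `V` the 20-term polynomial expansion of
#' the camera XYZ.
#'
#' @param model A `calibration_model` from [fit_correction_matrix()].
#' @param xyz_camera An `xyz_color` with camera provenance.
#' @return An `xyz_color` with corrected provenance.
#' @export
apply_correction <- function(model, xyz_camera) {
  if (!inherits(model, "calibration_model")) {
    stop("`model` must be a calibration_model", call. = FALSE)
  }
  if (!inherits(xyz_camera, "xyz_color") || xyz_camera$provenance != "camera") {
    stop("`xyz_camera` must be an xyz_color with camera provenance", call. = FALSE)
  }
  v <- model$C %*% expand_variable_vector(xyz_camera, alpha = model$alpha)
  xyz_color(v[1], v[2], v[3], provenance = "corrected")
}

# Vectorized correction: n x 3 camera XYZ -> n x 3 corrected XYZ.
apply_correction_matrix <- function(model, xyz_mat) {
  t(model$C %*% variable_matrix(xyz_mat, alpha = model$alpha))
}

#' Serialize a calibration model to JSON
#' @param model A `calibration_model`.
#' @param path Output JSON path.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(C = as.vector(t(model$C)),  # row-major
              alpha = model$alpha,
              n_patches = model$n_patches,
              pinv_tol = model$pinv_tol,
              nonlinearity_report = model$nonlinearity_report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a calibration model from JSON
#' @param path JSON path written by [write_calibration_json()].
#' @return A `calibration_model`.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(C = matrix(obj$C, nrow = 3, byrow = TRUE),
                 alpha = obj$alpha,
                 nonlinearity_report = obj$nonlinearity_report,
                 n_patches = obj$n_patches,
                 pinv_tol = obj$pinv_tol),
            class = "calibration_model")
}
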