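#' @keywords internal
"_PACKAGE"

# Fixed sampling grid shared by every spectrum in the package.
SPECTRUM_WL <- 380:780
SPECTRUM_N  <- length(SPECTRUM_WL)

#' Construct a spectrum on the 380-780 nm, 1 nm grid
#'
#' A `spectrum` holds 401 samples of either a unitless reflectance
#' (typically in \[0, 1.2\]), an illuminant spectral power distribution
#' (nonnegative, arbitrary units), or a reconstructed reflectance produced
#' by the spectral model.
#'
#' @param values Numeric vector of length 401 (380, 381, ..., 780 nm).
#' @param kind One of `"reflectance"`, `"illuminant"`, `"reconstructed"`.
#' @return An object of class `spectrum` with fields `wavelength_nm`,
#'   `values` and `kind`.
#' @examples
#' flat <- spectrum(rep(0.5, 401))
#' range(flat$wavelength_nm)
#' @export
spectrum <- function(values, kind = c("reflectance", "illuminant", "reconstructed")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != SPECTRUM_N) {
    stop("a spectrum must have exactly ", SPECTRUM_N, " samples (380-780 nm at 1 nm), got ",
         length(values), call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("spectrum values must be finite", call. = FALSE)
  }
  if (kind == "illuminant" && any(values < 0)) {
    stop("an illuminant spectral power distribution cannot be negative", call. = FALSE)
  }
  structure(list(wavelength_nm = SPECTRUM_WL, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, 380-780 nm @ 1 nm, range [%.4g, %.4g]>\n",
              x$kind, min(x$values), max(x$values)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

assert_spectrum <- function(x, arg = deparse(substitute(x))) {
  if (!is_spectrum(x)) stop("`", arg, "` must be a spectrum object", call. = FALSE)
  invisible(x)
}

#' Root-mean-square error between two spectra
#'
#' @param a,b Spectra on the shared 380-780 nm grid.
#' @return Nonnegative scalar: `sqrt(mean((a - b)^2))` over the 401 samples.
#' @examples
#' a <- spectrum(rep(0.4, 401)); b <- spectrum(rep(0.5, 401))
#' rmse_spectra(a, b)  # 0.1
#' @export
rmse_spectra <- function(a, b) {
  assert_spectrum(a); assert_spectrum(b)
  if (!identical(a$wavelength_nm, b$wavelength_nm)) {
    stop("spectra are not on the same wavelength grid", call. = FALSE)
  }
  sqrt(mean((a$values - b$values)^2))
}

#' Clip a reconstructed reflectance for display
#'
#' Reconstruction on a truncated PCA basis may slightly overshoot the
#' physical range; for display we clip to \[0, 1.2\]. Error metrics are
#' always computed on the unclipped values (clipping would bias them).
#'
#' @param x A spectrum.
#' @param lo,hi Clip bounds.
#' @return The clipped spectrum.
#' @export
clip_spectrum <- function(x, lo = 0, hi = 1.2) {
  assert_spectrum(x)
  spectrum(pmin(pmax(x$values, lo), hi), kind = x$kind)
}

#' Read a single spectrum from CSV
#'
#' Expects columns `wavelength_nm,value` covering 380-780 nm at 1 nm.
#'
#' @param path CSV file path.
#' @param kind Spectrum kind (see [spectrum()]).
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, kind = "reflectance") {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("expected columns wavelength_nm,value in ", path, call. = FALSE)
  }
  d <- d[order(d$wavelength_nm), ]
  if (!identical(as.integer(d$wavelength_nm), as.integer(SPECTRUM_WL))) {
    stop("wavelength grid in ", path, " is not 380-780 nm at 1 nm", call. = FALSE)
  }
  spectrum(d$value, kind = kind)
}

#' Write a single spectrum to CSV
#' @param x A spectrum.
#' @param path Output path.
#' @export
write_spectrum_csv <- function(x, path) {
  assert_spectrum(x)
  utils::write.csv(data.frame(wavelength_nm = x$wavelength_nm, value = x$values),
                   path, row.names = FALSE)
}

#' Read a multi-spectrum wide CSV
#'
#' First column `wavelength_nm`, then one column per patch/sample.
#'
#' @param path CSV file path.
#' @param kind Spectrum kind applied to every column.
#' @return A named list of `spectrum` objects, one per data column.
#' @export
read_spectra_csv <- function(path, kind = "reflectance") {
  d <- utils::read.csv(path)
  if (names(d)[1] != "wavelength_nm") {
    stop("first column of ", path, " must be wavelength_nm", call. = FALSE)
  }
  d <- d[order(d$wavelength_nm), ]
  if (!identical(as.integer(d$wavelength_nm), as.integer(SPECTRUM_WL))) {
    stop("wavelength grid in ", path, " is not 380-780 nm at 1 nm", call. = FALSE)
  }
  out <- lapply(d[-1], spectrum, kind = kind)
  names(out) <- names(d)[-1]
  out
}

#' Write a list of spectra as a wide CSV
#' @param spectra Named list of spectra.
#' @param path Output path.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  vals <- lapply(spectra, function(s) { assert_spectrum(s); s$values })
  d <- data.frame(wavelength_nm = SPECTRUM_WL, vals, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
}

# Matrix view: one spectrum per row (n x 401).
spectra_matrix <- function(spectra) {
  do.call(rbind, lapply(spectra, function(s) { assert_spectrum(s); s$values }))
}
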