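# Colorimetric kernel: CIE 1931 2-degree observer, tristimulus integration,
# sRGB decoding, L*a*b* conversion and the CIEDE2000 color difference.

#' Load the CIE 1931 2-degree color matching functions
#'
#' Returns the standard observer tabulated at 380-780 nm in 1 nm steps,
#' bundled with the package as a CSV.
#'
#' @param path Optional path to an alternative CMF table with columns
#'   `wavelength_nm,xbar,ybar,zbar` on the same grid.
#' @return A `cmf_set`: list with `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @examples
#' cmf <- load_cmf()
#' cmf$wavelength_nm[which.max(cmf$ybar)]  # luminous efficiency peaks near 555 nm
#' @export
load_cmf <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cie1931_cmf_2deg_1nm.csv", package = "dermspectra")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("color matching function table not found; package data is missing or corrupt",
         call. = FALSE)
  }
  d <- utils::read.csv(path)
  ok <- all(c("wavelength_nm", "xbar", "ybar", "zbar") %in% names(d)) &&
    nrow(d) == SPECTRUM_N &&
    identical(as.integer(d$wavelength_nm), as.integer(SPECTRUM_WL)) &&
    all(is.finite(as.matrix(d[c("xbar", "ybar", "zbar")]))) &&
    all(d$xbar >= 0) && all(d$ybar >= 0) && all(d$zbar >= 0)
  if (!ok) stop("color matching function table is corrupt: ", path, call. = FALSE)
  structure(list(wavelength_nm = SPECTRUM_WL,
                 xbar = d$xbar, ybar = d$ybar, zbar = d$zbar),
            class = "cmf_set")
}

#' Construct a tristimulus XYZ value
#'
#' XYZ coordinates on the Y in \[0, 100\] scale, tagged with the device that
#' produced them so that downstream steps can refuse to, e.g., apply the
#' camera correction twice.
#'
#' @param X,Y,Z Tristimulus components.
#' @param provenance `"camera"`, `"spectrometer"` or `"corrected"`.
#' @return An `xyz_color` object.
#' @export
xyz_color <- function(X, Y, Z, provenance = c("camera", "spectrometer", "corrected")) {
  provenance <- match.arg(provenance)
  v <- c(X = as.numeric(X), Y = as.numeric(Y), Z = as.numeric(Z))
  if (any(!is.finite(v))) stop("XYZ components must be finite", call. = FALSE)
  structure(list(X = v[["X"]], Y = v[["Y"]], Z = v[["Z"]], provenance = provenance),
            class = "xyz_color")
}

#' @export
print.xyz_color <- function(x, ...) {
  cat(sprintf("<XYZ %s: %.3f %.3f %.3f>\n", x$provenance, x$X, x$Y, x$Z))
  invisible(x)
}

xyz_vec <- function(x) c(x$X, x$Y, x$Z)

#' Integrate a reflectance spectrum to tristimulus XYZ
#'
#' Computes `X = k * sum(S * R * xbar)` (and likewise Y, Z) over the 1 nm
#' grid, with the brightness ratio `k = 100 / sum(S * ybar)` so that a
#' perfect white reflector (`R == 1`) maps to Y = 100 under any illuminant.
#' Integrals are evaluated as plain summation with a 1 nm step; at this
#' tabulation the choice of quadrature rule is negligible.
#'
#' @param R Reflectance spectrum.
#' @param S Illuminant spectral power distribution (spectrum of kind
#'   `"illuminant"`, not identically zero).
#' @param cmf A `cmf_set` from [load_cmf()].
#' @return A list with `xyz` (an `xyz_color` with spectrometer provenance)
#'   and `whitepoint` (list `k`, `Xn`, `Yn = 100`, `Zn` for the illuminant).
#' @examples
#' cmf <- load_cmf()
#' S <- daylight_illuminant()
#' spectrum_to_xyz(spectrum(rep(1, 401)), S, cmf)$xyz$Y  # exactly 100
#' @export
spectrum_to_xyz <- function(R, S, cmf = load_cmf()) {
  assert_spectrum(R); assert_spectrum(S)
  if (!inherits(cmf, "cmf_set")) stop("`cmf` must come from load_cmf()", call. = FALSE)
  s <- S$values
  denom <- sum(s * cmf$ybar)
  if (denom <= 0) stop("degenerate illuminant: S * ybar integrates to zero", call. = FALSE)
  k <- 100 / denom
  r <- R$values
  X <- k * sum(s * r * cmf$xbar)
  Y <- k * sum(s * r * cmf$ybar)
  Z <- k * sum(s * r * cmf$zbar)
  Xn <- k * sum(s * cmf$xbar)
  Zn <- k * sum(s * cmf$zbar)
  list(xyz = xyz_color(X, Y, Z, provenance = "spectrometer"),
       whitepoint = list(k = k, Xn = Xn, Yn = 100, Zn = Zn))
}

#' Whitepoint of an illuminant
#'
#' Convenience wrapper: tristimulus of the illuminant itself (perfect white
#' reflector), normalized to Yn = 100.
#'
#' @inheritParams spectrum_to_xyz
#' @return List with `k`, `Xn`, `Yn = 100`, `Zn`.
#' @export
illuminant_whitepoint <- function(S, cmf = load_cmf()) {
  spectrum_to_xyz(spectrum(rep(1, SPECTRUM_N)), S, cmf)$whitepoint
}

# sRGB (IEC 61966-2-1) linear RGB -> XYZ matrix, rows renormalized so that
# reference white maps to Y = 100 exactly on our scale.
srgb_matrix <- function() {
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  100 * m / sum(m[2, ])
}

# Vectorized core: n x 3 matrix of 8-bit channel values -> n x 3 XYZ.
srgb_to_xyz_matrix <- function(rgb255) {
  u <- rgb255 / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  lin %*% t(srgb_matrix())
}

# Inverse: n x 3 XYZ (Y in [0,100]) -> n x 3 8-bit sRGB. Out-of-gamut values
# are clipped to [0, 1] in linear RGB before companding.
xyz_to_srgb_matrix <- function(xyz, quantize = TRUE) {
  lin <- xyz %*% t(solve(srgb_matrix()))
  lin <- pmin(pmax(lin, 0), 1)
  u <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- u * 255
  if (quantize) out <- round(out)
  out
}

#' Decode an sRGB color to tristimulus XYZ
#'
#' Applies IEC 61966-2-1 inverse companding to the 8-bit channel values and
#' the standard sRGB/D65 primaries matrix, scaled so that white
#' `(255, 255, 255)` gives Y = 100. Gamma is decoded here because the
#' downstream polynomial correction matrix is meant to absorb residual,
#' device-specific nonlinearity -- not the known sRGB transfer curve.
#'
#' @param rgb Numeric triple of channel values in \[0, 255\].
#' @return An `xyz_color` with camera provenance.
#' @examples
#' srgb_to_xyz(c(255, 255, 255))$Y  # 100
#' @export
srgb_to_xyz <- function(rgb) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3 || anyNA(rgb) || any(rgb < 0) || any(rgb > 255)) {
    stop("`rgb` must be three channel values in [0, 255]", call. = FALSE)
  }
  v <- srgb_to_xyz_matrix(matrix(rgb, nrow = 1))
  xyz_color(v[1], v[2], v[3], provenance = "camera")
}

#' Convert XYZ to CIE L*a*b*
#'
#' Standard CIE formulation with the piecewise cube-root companding,
#' relative to the supplied whitepoint (derive it from the session
#' illuminant with [illuminant_whitepoint()]; D65 is not assumed).
#'
#' @param xyz An `xyz_color`.
#' @param wp Whitepoint list with positive `Xn`, `Zn` and `Yn = 100`.
#' @return A `lab_color`: list with `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz, wp) {
  if (!inherits(xyz, "xyz_color")) stop("`xyz` must be an xyz_color", call. = FALSE)
  if (is.null(wp$Xn) || is.null(wp$Yn) || is.null(wp$Zn) ||
      wp$Xn <= 0 || wp$Yn <= 0 || wp$Zn <= 0) {
    stop("whitepoint components must be positive", call. = FALSE)
  }
  if (abs(wp$Yn - 100) > 1e-9) stop("whitepoint must be normalized to Yn = 100", call. = FALSE)
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz$X / wp$Xn); fy <- f(xyz$Y / wp$Yn); fz <- f(xyz$Z / wp$Zn)
  lab_color(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

#' Construct a CIE L*a*b* color
#' @param L,a,b Lab coordinates.
#' @return A `lab_color` object.
#' @export
lab_color <- function(L, a, b) {
  v <- c(as.numeric(L), as.numeric(a), as.numeric(b))
  if (any(!is.finite(v))) stop("Lab components must be finite", call. = FALSE)
  structure(list(L = v[1], a = v[2], b = v[3]), class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("<Lab: %.2f %.2f %.2f>\n", x$L, x$a, x$b))
  invisible(x)
}

as_lab <- function(x) {
  if (inherits(x, "lab_color")) return(c(x$L, x$a, x$b))
  x <- as.numeric(x)
  if (length(x) != 3 || anyNA(x)) stop("expected a lab_color or numeric triple", call. = FALSE)
  x
}

#' CIEDE2000 color difference
#'
#' The CIE 2000 perceptually weighted color-difference formula between two
#' L*a*b* colors, with parametric factors kL = kC = kH = 1. Symmetric and
#' nonnegative; roughly one unit corresponds to a just-noticeable
#' difference.
#'
#' @param lab1,lab2 `lab_color` objects or numeric `(L, a, b)` triples.
#' @return Nonnegative scalar difference.
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # 2.0425
#' @export
ciede2000 <- function(lab1, lab2) {
  p <- as_lab(lab1); q <- as_lab(lab2)
  L1 <- p[1]; a1 <- p[2]; b1 <- p[3]
  L2 <- q[1]; a2 <- q[2]; b2 <- q[3]
  deg2rad <- pi / 180; rad2deg <- 180 / pi

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  hp <- function(b, ap) {
    if (b == 0 && ap == 0) return(0)
    h <- atan2(b, ap) * rad2deg
    if (h < 0) h + 360 else h
  }
  h1p <- hp(b1, a1p); h2p <- hp(b2, a2p)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0
         else if (abs(h2p - h1p) <= 180) h2p - h1p
         else if (h2p - h1p > 180) h2p - h1p - 360
         else h2p - h1p + 360
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * deg2rad / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p
         else if (abs(h1p - h2p) <= 180) (h1p + h2p) / 2
         else if (h1p + h2p < 360) (h1p + h2p + 360) / 2
         else (h1p + h2p - 360) / 2
  Tf <- 1 - 0.17 * cos((hbp - 30) * deg2rad) + 0.24 * cos(2 * hbp * deg2rad) +
    0.32 * cos((3 * hbp + 6) * deg2rad) - 0.20 * cos((4 * hbp - 63) * deg2rad)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tf
  RT <- -sin(2 * dtheta * deg2rad) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}
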