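# Image and mask handling: PNG IO, a classical stand-in lesion segmenter,
# segmentation metrics, and per-pixel hyperspectral cube construction.
#
# Images are numeric H x W x 3 arrays of 8-bit channel values (0..255).
# Masks are binary H x W matrices wrapped in the `lesion_mask` class; the
# class also accepts externally produced masks (e.g. from a trained deep
# segmenter), so the segmenter below is a pluggable stand-in, not the only
# mask source.

#' Construct a lesion mask
#'
#' @param grid H x W matrix with values in \{0, 1\} (or logical).
#' @param prob Optional H x W matrix of lesion probabilities in (0, 1).
#' @return A `lesion_mask` with fields `grid`, `lesion_fraction`, `prob`.
#' @export
lesion_mask <- function(grid, prob = NULL) {
  grid <- as.matrix(grid)
  if (is.logical(grid)) grid <- grid + 0
  if (!all(grid %in% c(0, 1))) stop("mask values must be 0 or 1", call. = FALSE)
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    if (!all(dim(prob) == dim(grid))) stop("prob dimensions must match the mask", call. = FALSE)
  }
  structure(list(grid = grid, lesion_fraction = mean(grid), prob = prob),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask: %d x %d, %.1f%% lesion>\n",
              nrow(x$grid), ncol(x$grid), 100 * x$lesion_fraction))
  invisible(x)
}

assert_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("`image` must be an H x W x 3 array of 8-bit channel values", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("image channel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

#' Segmentation parameters for the stand-in lesion segmenter
#'
#' @param c_mad Robust-threshold multiplier: a pixel is lesion when its
#'   redness statistic exceeds `median + c_mad * MAD` over the image.
#' @param brush_size Diameter (odd integer, pixels) of the disc brush used
#'   for the morphological open/close cleanup; 0 disables morphology.
#' @param stat_threshold Absolute threshold on the redness statistic;
#'   overrides the robust rule when not `NULL`.
#' @return Parameter list for [segment_lesion()].
#' @export
segment_params <- function(c_mad = 4, brush_size = 5, stat_threshold = NULL) {
  list(c_mad = c_mad, brush_size = brush_size, stat_threshold = stat_threshold)
}

# Normalized redness statistic (R - G) / (R + G). Erythematous lesions
# absorb green (hemoglobin) relative to red, and the ratio cancels
# multiplicative shading, so this single chroma axis separates lesion from
# surrounding skin coarsely -- which is all the downstream spectral
# classifier needs.
redness_statistic <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]
  (r - g) / (r + g + 1e-6)
}

#' Segment a lesion with a robust color threshold
#'
#' Classical stand-in segmenter: thresholds a redness opponent-color
#' statistic at `median + c_mad * MAD` (computed over the whole image, so
#' the majority skin background sets the reference), then cleans the binary
#' mask with a morphological opening and closing. Deterministic for fixed
#' parameters. Coarse segmentation is sufficient here: the mask only
#' delimits the region whose spectra are analyzed, and externally produced
#' masks can be supplied through [lesion_mask()] instead.
#'
#' @param image H x W x 3 array of 8-bit channel values.
#' @param params Parameter list from [segment_params()].
#' @return A `lesion_mask`; its `prob` field carries the pre-threshold
#'   statistic squashed to (0, 1), usable as a probability map for the
#'   cross-entropy metric.
#' @export
segment_lesion <- function(image, params = segment_params()) {
  assert_rgb_image(image)
  s <- redness_statistic(image)
  if (is.null(params$stat_threshold)) {
    thr <- stats::median(s) + params$c_mad * stats::mad(s)
  } else {
    thr <- params$stat_threshold
  }
  mask <- (s > thr) + 0
  if (params$brush_size >= 3 && any(mask == 1) && !all(mask == 1)) {
    brush <- EBImage::makeBrush(params$brush_size, shape = "disc")
    mask <- EBImage::closing(EBImage::opening(mask, brush), brush)
    mask <- (as.matrix(mask) > 0.5) + 0
  }
  scale <- max(stats::mad(s), 0.01)
  prob <- stats::plogis((s - thr) / scale)
  lesion_mask(mask, prob = prob)
}

#' Overlap and log-loss metrics between two masks
#'
#' @param pred Predicted `lesion_mask`.
#' @param truth Ground-truth `lesion_mask`.
#' @param prob Optional H x W probability map (defaults to `pred$prob` if
#'   present); required for the cross-entropy term.
#' @return A `segmentation_score`: `dice = 2|A∩B| / (|A| + |B|)`,
#'   `iou = |A∩B| / |A∪B|`, and `cross_entropy` (mean binary log loss of
#'   `prob` against the truth, `NA` when no probabilities are available).
#'   Two empty masks count as a perfect match (dice = iou = 1).
#' @export
segmentation_metrics <- function(pred, truth, prob = NULL) {
  stopifnot(inherits(pred, "lesion_mask"), inherits(truth, "lesion_mask"))
  if (!all(dim(pred$grid) == dim(truth$grid))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  a <- pred$grid; b <- truth$grid
  inter <- sum(a * b); sa <- sum(a); sb <- sum(b)
  dice <- if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
  union <- sa + sb - inter
  iou <- if (union == 0) 1 else inter / union
  if (is.null(prob)) prob <- pred$prob
  ce <- NA_real_
  if (!is.null(prob)) {
    if (!all(dim(prob) == dim(b))) stop("probability map dimensions differ", call. = FALSE)
    eps <- 1e-7
    p <- pmin(pmax(prob, eps), 1 - eps)
    ce <- -mean(b * log(p) + (1 - b) * log(1 - p))
  }
  structure(list(dice = dice, iou = iou, cross_entropy = ce),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("<segmentation: dice %.4f, IoU %.4f, cross-entropy %s>\n",
              x$dice, x$iou,
              if (is.na(x$cross_entropy)) "n/a" else sprintf("%.4f", x$cross_entropy)))
  invisible(x)
}

#' Convert an RGB image to a hyperspectral cube
#'
#' Per pixel: sRGB decode to camera XYZ, apply the correction matrix, and
#' reconstruct the 401-sample reflectance spectrum on the PCA basis. The
#' operation is purely per-pixel -- identical colors yield identical
#' spectra. Pixels outside the mask (when given) are set to `NA` (a
#' sentinel; zero is a valid reflectance and is never used to mark
#' exclusion).
#'
#' @param image H x W x 3 array of 8-bit channel values.
#' @param calib A `calibration_model`.
#' @param basis A `spectral_basis` carrying M.
#' @param mask Optional `lesion_mask`; pixels with mask 0 are excluded.
#' @return H x W x 401 numeric array of reflectance values (unclipped).
#' @export
image_to_cube <- function(image, calib, basis, mask = NULL) {
  assert_rgb_image(image)
  stopifnot(inherits(calib, "calibration_model"), inherits(basis, "spectral_basis"))
  if (is.null(basis$M)) {
    stop("basis is incomplete: fit_transformation_matrix() has not been run", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!is.null(mask) && !all(dim(mask$grid) == c(h, w))) {
    stop("mask dimensions do not match the image", call. = FALSE)
  }
  px <- matrix(image, nrow = h * w, ncol = 3)
  sel <- if (is.null(mask)) seq_len(h * w) else which(mask$grid == 1)
  spec <- matrix(NA_real_, h * w, SPECTRUM_N)
  if (length(sel) > 0) {
    xyz_cam <- srgb_to_xyz_matrix(px[sel, , drop = FALSE])
    xyz_cor <- apply_correction_matrix(calib, xyz_cam)
    spec[sel, ] <- reconstruct_matrix(basis, xyz_cor)
  }
  array(spec, dim = c(h, w, SPECTRUM_N))
}

#' Read an RGB image from PNG
#' @param path PNG path.
#' @return H x W x 3 array of channel values in \[0, 255\].
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) stop("expected an RGB image, got grayscale: ", path, call. = FALSE)
  a[, , 1:3, drop = FALSE] * 255
}

#' Write an RGB image to PNG
#' @param image H x W x 3 array of channel values in \[0, 255\].
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, path)
}

#' Read a binary mask from a single-channel PNG (0/255 convention)
#' @param path PNG path.
#' @return A `lesion_mask`.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  lesion_mask((a > 0.5) + 0)
}

#' Write a binary mask to a single-channel PNG (0/255 convention)
#' @param mask A `lesion_mask`.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  png::writePNG(array(as.numeric(mask$grid), dim = dim(mask$grid)), path)
}

#' Write a hyperspectral cube as flat binary with a JSON header
#'
#' Layout: float32 little-endian, wavelength fastest, then columns, then
#' rows; the header records dimensions and the wavelength grid.
#'
#' @param cube H x W x 401 array from [image_to_cube()].
#' @param path Output path for the binary; the header is written to
#'   `paste0(path, ".json")`.
#' @export
write_cube_bin <- function(cube, path) {
  stopifnot(is.array(cube), length(dim(cube)) == 3, dim(cube)[3] == SPECTRUM_N)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube, c(3, 2, 1))), con, size = 4, endian = "little")
  jsonlite::write_json(list(height = dim(cube)[1], width = dim(cube)[2],
                            bands = SPECTRUM_N, dtype = "float32",
                            wavelength_nm = SPECTRUM_WL),
                       paste0(path, ".json"), auto_unbox = TRUE)
}

#' Read a hyperspectral cube written by [write_cube_bin()]
#' @param path Binary path (header expected at `paste0(path, ".json")`).
#' @return H x W x 401 array.
#' @export
read_cube_bin <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- hdr$height * hdr$width * hdr$bands
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  aperm(array(v, dim = c(hdr$bands, hdr$width, hdr$height)), c(3, 2, 1))
}
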