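#' Calibrated 2-D grayscale image
#'
#' A thin wrapper around a numeric matrix carrying the physical pixel size
#' in micrometers and the nominal bit depth of the acquisition. Rows are the
#' image y axis, columns the x axis (matrix convention).
#'
#' @param values Numeric matrix of non-negative intensities.
#' @param pixel_size_um Pixel size in micrometers (> 0).
#' @param bit_depth Nominal bit depth, 8 or 16. Determines the gray-level
#'   range `[0, 2^bit_depth - 1]` used by contrast enhancement and by the
#'   histogram-based thresholds.
#' @return An `image2d` object (numeric matrix with attributes).
#' @export
image2d <- function(values, pixel_size_um, bit_depth = 16L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  structure(values,
            pixel_size_um = as.numeric(pixel_size_um),
            bit_depth = as.integer(bit_depth),
            class = c("image2d", class(values)))
}

#' Binary mask aligned to an image
#'
#' @param values Logical matrix.
#' @param pixel_size_um Pixel size in micrometers (> 0).
#' @return A `binary_mask` object (logical matrix with attributes).
#' @export
binary_mask <- function(values, pixel_size_um) {
  if (!is.matrix(values) || !is.logical(values))
    stop("`values` must be a logical matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(values,
            pixel_size_um = as.numeric(pixel_size_um),
            class = c("binary_mask", class(values)))
}

#' Pixel size of an image or mask
#' @param x An `image2d` or `binary_mask`.
#' @return Pixel size in micrometers.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) stop("object carries no pixel size")
  ps
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px, %.4g um/px, %d-bit, range [%g, %g]\n",
              nrow(x), ncol(x), pixel_size(x), bit_depth(x),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %.4g um/px, %d foreground px\n",
              nrow(x), ncol(x), pixel_size(x), sum(x)))
  invisible(x)
}

bit_depth <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 16L else bd
}

gray_max <- function(img) 2^bit_depth(img) - 1

# Rebuild an image2d with new values but the calibration of `template`.
same_geometry <- function(values, template) {
  image2d(values, pixel_size(template), bit_depth(template))
}

check_same_shape <- function(a, b, what = "inputs") {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop(sprintf("%s differ in shape: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)))
  pa <- attr(a, "pixel_size_um"); pb <- attr(b, "pixel_size_um")
  if (!is.null(pa) && !is.null(pb) && abs(pa - pb) > 1e-9)
    stop(sprintf("%s differ in calibration: %g vs %g um/px", what, pa, pb))
  invisible(TRUE)
}

# strip classes/attrs for raw matrix math
as_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
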