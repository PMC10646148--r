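## Channel filtering and the two-mask neurite segmentation.
##
## The workflow mirrors a semi-automated ImageJ routine for motor-neuron
## cultures: nuclei are segmented from the DAPI channel (Huang threshold,
## small-object removal, disk expansion), while the neurite marker channel
## is duplicated into a high-intensity branch (contrast enhancement,
## Gaussian blur, Moments threshold) and a ridge branch (contrast
## enhancement, Laplacian-of-Gaussian, Moments threshold); their union minus
## the expanded soma mask is the final neurite mask.

#' Masking parameters
#'
#' @param saturated_fraction Total fraction of pixels saturated by contrast
#'   enhancement (half at each tail). Default 0.001 (0.1%).
#' @param blur_sigma_um Gaussian blur sigma in micrometers for the
#'   high-intensity branch. Default 2.
#' @param log_sigma_um Laplacian-of-Gaussian scale in micrometers for the
#'   ridge branch. The source workflow names no scale; the default (0.6 um,
#'   about 3 px at the default calibration) is matched to the 1-3 px,
#'   PSF-broadened neurite profiles the ridge mask exists to recover:
#'   large enough that a ridge thins to a single centerline, small enough
#'   to resolve neighboring branches.
#' @param min_outlier_radius_px Connected components of the nuclei mask with
#'   equivalent-circle radius below this many pixels are discarded.
#'   Default 20.
#' @param nuclei_expand_px Euclidean dilation radius (pixels) applied to the
#'   nuclei mask to cover the thin cytoplasmic rim of mature motor neurons.
#'   Default 5.
#' @param neurite_min_component_px Despeckle cutoff: 8-connected components
#'   of the final neurite mask smaller than this area (pixels) are removed.
#'   At the default calibration 50 px is about 2 um^2, far below any
#'   resolvable neurite fragment but above the blob size of shot-noise
#'   speckle surviving the ridge threshold. Default 50; 0 disables.
#' @param nuclei_threshold_method Threshold for the nuclear channel;
#'   only `"huang"` is supported.
#' @param intensity_threshold_method Threshold for the marker branches;
#'   only `"moments"` is supported.
#' @return A list of class `masking_params`.
#' @export
masking_params <- function(saturated_fraction = 0.001,
                           blur_sigma_um = 2,
                           log_sigma_um = 0.6,
                           min_outlier_radius_px = 20,
                           nuclei_expand_px = 5,
                           neurite_min_component_px = 50,
                           nuclei_threshold_method = "huang",
                           intensity_threshold_method = "moments") {
  stopifnot(saturated_fraction >= 0, saturated_fraction < 1,
            blur_sigma_um > 0, log_sigma_um > 0,
            min_outlier_radius_px >= 0, nuclei_expand_px >= 0,
            neurite_min_component_px >= 0)
  nuclei_threshold_method <- match.arg(nuclei_threshold_method, "huang")
  intensity_threshold_method <- match.arg(intensity_threshold_method, "moments")
  structure(list(saturated_fraction = saturated_fraction,
                 blur_sigma_um = blur_sigma_um,
                 log_sigma_um = log_sigma_um,
                 min_outlier_radius_px = min_outlier_radius_px,
                 nuclei_expand_px = nuclei_expand_px,
                 neurite_min_component_px = neurite_min_component_px,
                 nuclei_threshold_method = nuclei_threshold_method,
                 intensity_threshold_method = intensity_threshold_method),
            class = "masking_params")
}

#' Maximum-intensity projection
#'
#' Collapse a z-stack to a single plane by taking the per-pixel maximum
#' across planes.
#'
#' @param stack A list of `image2d` planes with identical shape and
#'   calibration.
#' @return An `image2d`.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || !length(stack)) stop("`stack` must be a non-empty list")
  ref <- stack[[1]]
  out <- as_matrix(ref)
  for (p in stack[-1]) {
    check_same_shape(ref, p, "stack planes")
    out <- pmax(out, as_matrix(p))
  }
  same_geometry(out, ref)
}

#' Linear contrast enhancement with tail saturation
#'
#' Clips the stated total fraction of pixels (half at each intensity tail,
#' bounds taken as order statistics of the sorted pixel values) and linearly
#' rescales to the full gray-level range of the image's bit depth, rounding
#' to integer levels. Order-preserving on non-clipped pixels. A constant
#' image is returned unchanged with a notice.
#'
#' @param img An `image2d`.
#' @param saturated_fraction Total fraction of saturated pixels in `[0, 1)`.
#' @return An `image2d` spanning `[0, 2^bit_depth - 1]`.
#' @export
enhance_contrast <- function(img, saturated_fraction = 0.001) {
  stopifnot(saturated_fraction >= 0, saturated_fraction < 1)
  v <- as.numeric(img)
  n <- length(v)
  s <- sort(v)
  m <- round(n * saturated_fraction / 2)
  lo <- if (m >= 1) s[m] else s[1]
  hi <- if (m >= 1) s[n - m + 1] else s[n]
  if (hi <= lo) {
    message("enhance_contrast: constant image, returned unchanged")
    return(img)
  }
  mx <- gray_max(img)
  out <- (as_matrix(img) - lo) / (hi - lo) * mx
  out <- round(pmin(pmax(out, 0), mx))
  same_geometry(out, img)
}

gaussian_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

#' Gaussian blur with physically calibrated sigma
#'
#' Separable normalized Gaussian convolution; `sigma` is given in
#' micrometers and converted to pixels through the image calibration
#' (`sigma_px = sigma_um / pixel_size_um`). Reflective boundary handling
#' keeps the mean intensity stable.
#'
#' @param img An `image2d`.
#' @param sigma_um Standard deviation in micrometers (> 0).
#' @return A real-valued `image2d`.
#' @export
gaussian_blur <- function(img, sigma_um) {
  stopifnot(sigma_um > 0)
  k <- gaussian_kernel_1d(sigma_um / pixel_size(img))
  same_geometry(.sep_convolve(as_matrix(img), k, k), img)
}

#' Laplacian-of-Gaussian ridge filter
#'
#' Band-pass response emphasizing thin bright structures at scale
#' `sigma_um`. The raw Laplacian is negated so bright ridges and blobs on a
#' dark background yield positive response. Computed separably as
#' `-(G''_x * G_y + G_x * G''_y)` with reflective boundaries; the response
#' is real-valued (use [rescale_to_range()] before histogram thresholding).
#'
#' @param img An `image2d`.
#' @param sigma_um Filter scale in micrometers (> 0).
#' @return A real-valued `image2d` (signed response).
#' @export
log_filter <- function(img, sigma_um) {
  stopifnot(sigma_um > 0)
  s <- sigma_um / pixel_size(img)
  r <- max(2L, ceiling(4 * s))
  x <- (-r):r
  g <- exp(-x^2 / (2 * s^2))
  g <- g / sum(g)
  # second derivative of the (normalized) sampled Gaussian, zero-mean
  # corrected so a constant image gives exactly zero response
  d2g <- g * (x^2 - s^2) / s^4
  d2g <- d2g - mean(d2g)
  m <- as_matrix(img)
  resp <- .sep_convolve(m, d2g, g) + .sep_convolve(m, g, d2g)
  same_geometry(-resp, img)
}

#' Rescale a real-valued image to its gray-level range
#'
#' Min-max rescale to `[0, 2^bit_depth - 1]` with rounding to integer
#' levels; used to bring a real-valued filter response back onto the
#' histogram grid expected by the threshold operators.
#'
#' @param img An `image2d`.
#' @return An integer-valued `image2d`.
#' @export
rescale_to_range <- function(img) {
  v <- as_matrix(img)
  lo <- min(v); hi <- max(v)
  mx <- gray_max(img)
  if (hi <= lo) return(same_geometry(array(0, dim(v)), img))
  same_geometry(round((v - lo) / (hi - lo) * mx), img)
}

#' Quantize a signed filter response to 8-bit for thresholding
#'
#' Min-max rescale of a real-valued (e.g. Laplacian-of-Gaussian) response
#' to 256 gray levels -- the conversion an interactive workflow performs
#' when it turns a float filter result into a displayable 8-bit image
#' before running an automatic threshold. The coarse binning makes the
#' histogram robust: the narrow background-noise lobe of a band-pass
#' response collapses into a few bins, so the moment-preserving threshold
#' separates the positive ridge tail instead of splitting the noise lobe.
#'
#' @param img A real-valued `image2d` (signed response).
#' @return An 8-bit `image2d` with values in `[0, 255]`.
#' @export
rescale_to_8bit <- function(img) {
  v <- as_matrix(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(image2d(array(0, dim(v)), pixel_size(img), 8L))
  image2d(round((v - lo) / (hi - lo) * 255), pixel_size(img), 8L)
}

#' Remove small connected components
#'
#' Deletes 8-connected foreground components whose equivalent-circle radius
#' `sqrt(area / pi)` is below `min_radius_px`; all other components are
#' untouched.
#'
#' @param mask A `binary_mask`.
#' @param min_radius_px Radius cutoff in pixels (>= 0).
#' @return A `binary_mask`.
#' @export
remove_small_components <- function(mask, min_radius_px) {
  stopifnot(min_radius_px >= 0)
  if (min_radius_px == 0 || !any(mask)) return(mask)
  lab <- .label8(as_matrix(mask))
  n <- max(lab)
  if (n == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- sqrt(areas / pi) >= min_radius_px
  out <- array(FALSE, dim(mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  binary_mask(out, pixel_size(mask))
}

#' Expand a mask by a Euclidean disk
#'
#' Morphological dilation under the exact Euclidean-distance criterion: the
#' output contains every pixel whose center lies within `by_px` pixels of a
#' foreground pixel center. `by_px = 0` is the identity.
#'
#' @param mask A `binary_mask`.
#' @param by_px Expansion radius in pixels (>= 0).
#' @return A `binary_mask`.
#' @export
expand_mask <- function(mask, by_px) {
  stopifnot(by_px >= 0)
  if (by_px == 0 || !any(mask)) return(mask)
  d <- .distance_to_mask(as_matrix(mask))
  binary_mask(d <= by_px + 1e-9, pixel_size(mask))
}

#' Nuclei and soma masks from the nuclear channel
#'
#' Pipeline: Huang threshold on the DAPI channel, removal of components with
#' equivalent radius below `min_outlier_radius_px`, then Euclidean expansion
#' by `nuclei_expand_px` to cover the thin cytoplasmic rim around each
#' nucleus. Both the pre-expansion nuclei mask (used for soma counting) and
#' the expanded soma mask (subtracted from the neurite mask) are returned.
#'
#' @param dapi Nuclear-channel `image2d`.
#' @param params A [masking_params()] list.
#' @return A list with elements `nuclei` (pre-expansion `binary_mask`) and
#'   `soma` (expanded `binary_mask`).
#' @export
build_nuclei_mask <- function(dapi, params = masking_params()) {
  thr <- threshold_huang(dapi)
  raw <- apply_threshold(dapi, thr)
  nuclei <- remove_small_components(raw, params$min_outlier_radius_px)
  soma <- expand_mask(nuclei, params$nuclei_expand_px)
  list(nuclei = nuclei, soma = soma, threshold = thr)
}

#' Final neurite mask from the marker channel
#'
#' The marker channel is duplicated and processed along two independent
#' branches, each starting from its own contrast-enhanced copy:
#' a high-intensity mask (Gaussian blur then Moments threshold), capturing
#' somata, axon hillocks and bright neurite cores; and a ridge mask
#' (Laplacian-of-Gaussian then Moments threshold), capturing the thin, faint
#' distal segments. The final mask is the union of the two minus the
#' expanded soma mask, hence always disjoint from it. A blank marker channel
#' yields an empty mask without error.
#'
#' @param map2 Marker-channel `image2d` (e.g. Map2).
#' @param soma_mask Expanded soma `binary_mask` from [build_nuclei_mask()].
#' @param params A [masking_params()] list.
#' @return A `binary_mask` disjoint from `soma_mask`.
#' @export
build_neurite_mask <- function(map2, soma_mask, params = masking_params()) {
  check_same_shape(map2, soma_mask, "map2 and soma mask")
  empty <- binary_mask(array(FALSE, dim(map2)), pixel_size(map2))
  if (min(map2) >= max(map2)) {
    message("build_neurite_mask: blank marker channel, empty mask")
    return(empty)
  }
  high_src <- rescale_to_range(
    gaussian_blur(enhance_contrast(map2, params$saturated_fraction),
                  params$blur_sigma_um))
  high <- apply_threshold(high_src, threshold_moments(high_src))
  log_src <- rescale_to_8bit(
    log_filter(enhance_contrast(map2, params$saturated_fraction),
               params$log_sigma_um))
  # neurites are sparse, so the modal response level and the contiguous
  # lobe of comparably full bins around it are background; floor the
  # threshold at the lobe's upper edge so quantization jitter of the
  # narrow noise lobe can never tip part of it into the foreground
  h <- occupied_histogram(log_src)
  mi <- which.max(h$counts)
  edge <- mi
  while (edge < length(h$levels) &&
         h$counts[edge + 1] >= 0.02 * h$counts[mi] &&
         h$levels[edge + 1] == h$levels[edge] + 1)
    edge <- edge + 1
  ridge <- apply_threshold(log_src,
                           max(threshold_moments(log_src), h$levels[edge]))
  out <- binary_mask((as_matrix(high) | as_matrix(ridge)) &
                       !as_matrix(soma_mask),
                     pixel_size(map2))
  remove_small_area(out, params$neurite_min_component_px)
}

# area-based despeckle of a binary mask (8-connected components)
remove_small_area <- function(mask, min_area_px) {
  if (min_area_px <= 0 || !any(mask)) return(mask)
  lab <- .label8(as_matrix(mask))
  n <- max(lab)
  if (n == 0L) return(mask)
  keep <- tabulate(lab[lab > 0L], nbins = n) >= min_area_px
  out <- array(FALSE, dim(mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  binary_mask(out, pixel_size(mask))
}
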