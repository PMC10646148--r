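## Automatic histogram thresholds.
##
## All three methods are functions of the gray-level histogram only, computed
## on the native integer levels of the image (256 levels for 8-bit input,
## 65,536 for 16-bit), never on a rescaled copy. The shared foreground
## convention is "strictly above threshold"; ties go to background.

# histogram over occupied integer levels; values are rounded to integers
occupied_histogram <- function(img) {
  v <- round(as.numeric(img))
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty image")
  tab <- table(v)
  levels <- as.numeric(names(tab))
  list(levels = levels, counts = as.numeric(tab))
}

check_nondegenerate <- function(h) {
  if (length(h$levels) < 2L)
    stop("degenerate histogram: image has a single gray level, no threshold exists")
  invisible(h)
}

#' Huang minimum-fuzziness threshold
#'
#' Automatic threshold minimizing the Huang & Wang fuzziness measure: for a
#' candidate threshold the image is split at it, each pixel receives a
#' membership `1 / (1 + |g - mu_class| / C)` to its class mean (`C` = occupied
#' gray-level range), and the Shannon entropy of the memberships, accumulated
#' over the histogram, scores the candidate. The exhaustive scan over all
#' occupied gray levels returns the minimizer (ties broken toward the lowest
#' level). Foreground is the set of pixels strictly above the returned value.
#'
#' @param img An `image2d` (or numeric matrix) with at least two distinct
#'   gray levels.
#' @return The threshold gray level (numeric scalar).
#' @export
threshold_huang <- function(img) {
  h <- check_nondegenerate(occupied_histogram(img))
  .huang_scan(h$levels, h$counts)$threshold
}

#' Moment-preserving (Tsai) threshold
#'
#' Tsai's deterministic method: choose the binarization whose two-level image
#' preserves the first three gray-level moments of the input histogram. The
#' moment equations give the target fraction `p0` of below-threshold pixels;
#' the threshold is the lowest gray level at which the cumulative histogram
#' reaches `p0`. Foreground is strictly above the threshold.
#'
#' @inheritParams threshold_huang
#' @return The threshold gray level (numeric scalar).
#' @export
threshold_moments <- function(img) {
  h <- check_nondegenerate(occupied_histogram(img))
  p0 <- moments_target_fraction(h)
  cumfrac <- cumsum(h$counts) / sum(h$counts)
  i <- which(cumfrac >= p0 - 1e-12)[1]
  if (is.na(i)) i <- length(h$levels)
  # threshold must leave a non-empty foreground
  i <- min(i, length(h$levels) - 1L)
  h$levels[max(i, 1L)]
}

# Tsai's moment equations: fraction of pixels assigned to the lower level.
moments_target_fraction <- function(h) {
  p <- h$counts / sum(h$counts)
  g <- h$levels
  m1 <- sum(p * g); m2 <- sum(p * g^2); m3 <- sum(p * g^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram: zero variance")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (abs(z1 - z0) < .Machine$double.eps) return(0.5)
  (z1 - m1) / (z1 - z0)
}

#' IsoData (intermeans) threshold
#'
#' The stock iterative "default" automatic threshold: starting from the
#' global mean, repeatedly set the threshold to the average of the means of
#' the two classes it induces, until stable. Used as the default marker
#' binarization in per-cell scoring.
#'
#' @inheritParams threshold_huang
#' @return The threshold gray level (numeric scalar).
#' @export
threshold_isodata <- function(img) {
  h <- check_nondegenerate(occupied_histogram(img))
  g <- h$levels; w <- h$counts
  t <- sum(w * g) / sum(w)
  for (it in 1:1000) {
    lo <- g <= t
    if (!any(lo) || all(lo)) break
    t_new <- 0.5 * (sum(w[lo] * g[lo]) / sum(w[lo]) +
                    sum(w[!lo] * g[!lo]) / sum(w[!lo]))
    if (abs(t_new - t) < 1e-9) { t <- t_new; break }
    t <- t_new
  }
  # snap to the highest occupied level <= t so that "strictly above"
  # reproduces the class split the iteration converged to
  cand <- g[g <= t]
  if (!length(cand)) cand <- g[1]
  max(cand)
}

# shared dispatcher for configurable automatic thresholds
auto_threshold <- function(img, method = c("isodata", "huang", "moments")) {
  method <- match.arg(method)
  switch(method,
         isodata = threshold_isodata(img),
         huang = threshold_huang(img),
         moments = threshold_moments(img))
}

# apply a threshold with the package-wide foreground convention
apply_threshold <- function(img, threshold) {
  binary_mask(as_matrix(img) > threshold, pixel_size(img))
}
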