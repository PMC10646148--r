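## Per-cell marker scoring: mean intensities on maximum-intensity
## projections and double-positive cell fractions from automatically
## thresholded marker channels, with the nucleus-derived regions as the
## single cell universe for the "percentage of total cells" denominator.

#' Cell-scoring parameters
#'
#' @param auto_threshold_method Automatic threshold for marker
#'   binarization: `"isodata"` (the stock default), `"huang"` or
#'   `"moments"`.
#' @param min_particle_area_px Nuclei components below this area are
#'   discarded before scoring.
#' @param positive_fraction A cell is positive in a channel when at least
#'   this fraction of its region pixels is foreground. Default 0.5.
#' @param n_cells_per_group,n_groups Optional subsampled counting design
#'   (groups of cells drawn at random without replacement), mirroring
#'   manual scoring of a fixed number of cells per field group.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(auto_threshold_method = c("isodata", "huang",
                                                     "moments"),
                           min_particle_area_px = 50,
                           positive_fraction = 0.5,
                           n_cells_per_group = 60L,
                           n_groups = 3L) {
  auto_threshold_method <- match.arg(auto_threshold_method)
  stopifnot(min_particle_area_px >= 0,
            positive_fraction > 0, positive_fraction <= 1,
            n_cells_per_group >= 1, n_groups >= 1)
  structure(list(auto_threshold_method = auto_threshold_method,
                 min_particle_area_px = min_particle_area_px,
                 positive_fraction = positive_fraction,
                 n_cells_per_group = as.integer(n_cells_per_group),
                 n_groups = as.integer(n_groups)),
            class = "scoring_params")
}

#' Segment cell regions from the nuclear channel
#'
#' Huang threshold on the nuclear channel, removal of components below
#' `min_particle_area_px`, 8-connected labeling. Regions are disjoint by
#' construction; a blank channel yields an empty set.
#'
#' @param nuclei Nuclear-channel `image2d`.
#' @param params A [scoring_params()] list.
#' @return A list of class `cell_regions`: `labels` (integer matrix) and
#'   `records` (data.frame `cell_id`, `centroid_row`, `centroid_col`,
#'   `area_px`).
#' @export
segment_cells <- function(nuclei, params = scoring_params()) {
  empty <- structure(list(labels = array(0L, dim(nuclei)),
                          records = data.frame(cell_id = integer(0),
                                               centroid_row = numeric(0),
                                               centroid_col = numeric(0),
                                               area_px = integer(0))),
                     class = "cell_regions")
  if (min(nuclei) >= max(nuclei)) return(empty)
  mask <- apply_threshold(nuclei, threshold_huang(nuclei))
  lab <- .label8(as_matrix(mask))
  n <- max(lab)
  if (n == 0L) return(empty)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= params$min_particle_area_px)
  if (!length(keep)) return(empty)
  relab <- integer(n); relab[keep] <- seq_along(keep)
  labels <- array(0L, dim(lab))
  pos <- lab > 0L
  labels[pos] <- relab[lab[pos]]
  idx <- which(labels > 0L)
  nr <- nrow(labels)
  ids <- labels[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  records <- data.frame(
    cell_id = seq_along(keep),
    centroid_row = as.numeric(tapply(rows, ids, mean)),
    centroid_col = as.numeric(tapply(cols, ids, mean)),
    area_px = as.integer(tabulate(ids, nbins = length(keep))))
  structure(list(labels = labels, records = records), class = "cell_regions")
}

#' Mean marker intensity per cell region
#'
#' @param regions A `cell_regions` from [segment_cells()].
#' @param channel An `image2d` co-registered with the regions.
#' @return The `records` data.frame with a `mean_intensity` column added.
#' @export
measure_intensity <- function(regions, channel) {
  rec <- regions$records
  if (!nrow(rec)) { rec$mean_intensity <- numeric(0); return(rec) }
  if (!all(dim(regions$labels) == dim(channel)))
    stop("channel and regions differ in shape")
  idx <- which(regions$labels > 0L)
  ids <- regions$labels[idx]
  sums <- rowsum(as.numeric(channel)[idx], ids)
  rec$mean_intensity <- as.numeric(sums) / rec$area_px
  rec
}

#' Double-positive cell fraction from two marker channels
#'
#' Each marker channel is binarized with the configured automatic
#' threshold; a cell counts as positive in a channel when at least
#' `positive_fraction` of its region pixels is foreground, and
#' double-positive when positive in both. Optionally, the counting is
#' repeated on random subsamples (`n_groups` groups of
#' `n_cells_per_group` cells, seeded) to mimic manual scoring designs.
#'
#' @param regions A `cell_regions` from [segment_cells()].
#' @param chat,islet1 Marker `image2d`s co-registered with the regions.
#' @param params A [scoring_params()] list.
#' @param subsample If `TRUE`, also return per-group subsampled fractions.
#' @param seed Seed for the subsampling draw.
#' @return A list: `fraction` (double-positive / total), `cells`
#'   (data.frame with per-channel positivity flags), and when subsampling
#'   is requested `group_fractions` (numeric vector).
#' @export
classify_double_positive <- function(regions, chat, islet1,
                                     params = scoring_params(),
                                     subsample = FALSE, seed = 1L) {
  rec <- regions$records
  if (!nrow(rec)) stop("no cell regions to classify")
  pos_flags <- function(channel) {
    thr <- auto_threshold(channel, params$auto_threshold_method)
    fg <- as_matrix(channel) > thr
    idx <- which(regions$labels > 0L)
    ids <- regions$labels[idx]
    fgsum <- rowsum(as.numeric(fg[idx]), ids)
    as.numeric(fgsum) / rec$area_px >= params$positive_fraction
  }
  rec$chat_positive <- pos_flags(chat)
  rec$islet1_positive <- pos_flags(islet1)
  rec$double_positive <- rec$chat_positive & rec$islet1_positive
  out <- list(fraction = mean(rec$double_positive), cells = rec)
  if (subsample) {
    n <- nrow(rec)
    size <- min(params$n_cells_per_group, n)
    set.seed(seed)
    out$group_fractions <- vapply(seq_len(params$n_groups), function(g) {
      mean(rec$double_positive[sample.int(n, size)])
    }, numeric(1))
  }
  out
}
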