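## TIFF / CSV / JSON interfaces.
##
## Acquisitions are written as paired single-channel TIFFs
## (`<id>_dapi.tif`, `<id>_map2.tif`); ground truth as a JSON graph plus a
## true-metrics CSV; a manifest CSV records group / replicate / seed per
## image. Reading restores the calibrated two-channel acquisition.

write_channel_tiff <- function(img, path) {
  mx <- gray_max(img)
  tiff::writeTIFF(as_matrix(img) / mx, path,
                  bits.per.sample = bit_depth(img), compression = "none")
  invisible(path)
}

#' Write an acquisition as two single-channel TIFFs
#'
#' @param acq An `acquisition`.
#' @param dir Output directory (created if missing).
#' @param id Basename; files are `<id>_dapi.tif` and `<id>_map2.tif`.
#' @return Invisibly, the two file paths.
#' @export
write_acquisition <- function(acq, dir, id = "acq") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- file.path(dir, paste0(id, "_dapi.tif"))
  pm <- file.path(dir, paste0(id, "_map2.tif"))
  write_channel_tiff(acq$dapi, pd)
  write_channel_tiff(acq$map2, pm)
  invisible(c(dapi = pd, map2 = pm))
}

#' Read an acquisition from paired TIFFs
#'
#' @param dapi_path,map2_path Single-channel TIFF paths.
#' @param pixel_size_um Calibration (TIFF tags are not relied upon).
#' @param bit_depth Bit depth of the stored data (8 or 16).
#' @return An `acquisition`.
#' @export
read_acquisition <- function(dapi_path, map2_path, pixel_size_um,
                             bit_depth = 16L) {
  rd <- function(path) {
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    image2d(v, pixel_size_um, bit_depth)
  }
  dapi <- rd(dapi_path); map2 <- rd(map2_path)
  check_same_shape(dapi, map2, "dapi and map2")
  structure(list(dapi = dapi, map2 = map2, pixel_size_um = pixel_size_um,
                 provenance = c(dapi = dapi_path, map2 = map2_path)),
            class = "acquisition")
}

#' Write ground truth (graph JSON + true-metrics CSV)
#'
#' @param truth A `truth` list from [generate_acquisition()].
#' @param dir Output directory.
#' @param id Basename.
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(truth, dir, id = "acq") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pj <- file.path(dir, paste0(id, "_truth.json"))
  pc <- file.path(dir, paste0(id, "_truth.csv"))
  graph <- list(cell_centers = truth$cell_centers,
                nodes = truth$nodes,
                edges = lapply(truth$edges, function(e)
                  list(from = e$from, to = e$to,
                       poly = unname(as.matrix(e$poly)))))
  jsonlite::write_json(graph, pj, digits = 10, auto_unbox = TRUE)
  utils::write.csv(truth$true_metrics, pc, row.names = FALSE)
  invisible(c(json = pj, csv = pc))
}

#' Write a cohort to disk (TIFF pairs, truths, manifest)
#'
#' @param cohort A `cohort` from [generate_group()].
#' @param dir Output directory.
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(e) {
    write_acquisition(e$acquisition, dir, e$image_id)
    write_ground_truth(e$truth, dir, e$image_id)
    data.frame(image_id = e$image_id, group = e$group,
               replicate = e$replicate,
               seed = e$acquisition$provenance$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write per-acquisition morphometry records to CSV
#'
#' One row per acquisition: image id, group, replicate, counts and lengths.
#'
#' @param metrics Data.frame of `morphometry_record` rows.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
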