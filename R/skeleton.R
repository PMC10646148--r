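## Skeletonization and skeleton-graph morphometry.
##
## The neurite mask is thinned to unit-width 8-connected centerlines with a
## sequential Zhang-Suen-class algorithm (column-major scan order within
## each directional sub-iteration, connectivity re-checked before every
## deletion, iterated to a fixed point), then skeleton pixels are classified
## by their 8-neighbor count -- endpoint (1), slab (2), junction (>= 3) --
## with mutually adjacent junction pixels merged into single junction
## clusters, and branches traced as maximal slab paths between terminals.

#' Skeletonize a binary mask
#'
#' Topology-preserving thinning to unit-width, 8-connected centerlines.
#' The skeleton is a subset of the mask, preserves the number of
#' 8-connected components exactly, and the operator is idempotent.
#'
#' @param mask A `binary_mask`.
#' @return A `binary_mask` containing the skeleton.
#' @export
skeletonize <- function(mask) {
  binary_mask(.thin_skeleton(as_matrix(mask)), pixel_size(mask))
}

#' Classify skeleton pixels and cluster junctions
#'
#' Pixels of a unit-width skeleton are classified by their number of
#' 8-connected skeleton neighbors: `endpoint` (1), `slab` (2), `junction`
#' (3 or more). Isolated single pixels (0 neighbors) are recorded
#' separately and excluded from branch statistics. Mutually adjacent
#' junction pixels are merged into one junction cluster, each cluster
#' counting as a single junction node.
#'
#' @param skeleton A `binary_mask` as returned by [skeletonize()].
#' @return A list of class `skeleton_graph` with the skeleton, the pixel
#'   classification, the junction-cluster labels and (before
#'   [extract_branches()]) an empty branch table.
#' @export
classify_voxels <- function(skeleton) {
  m <- as_matrix(skeleton)
  nb <- .neighbor_count8(m)
  cls <- array("", dim(m))
  cls[m & nb == 1L] <- "endpoint"
  cls[m & nb == 2L] <- "slab"
  cls[m & nb >= 3L] <- "junction"
  cls[m & nb == 0L] <- "isolated"
  jmask <- array(m & nb >= 3L, dim(m))
  jlab <- .label8(jmask)
  structure(list(skeleton = skeleton,
                 class = cls,
                 junction_labels = jlab,
                 n_junction_clusters = max(jlab),
                 n_endpoints = sum(cls == "endpoint"),
                 n_isolated = sum(cls == "isolated"),
                 branches = NULL),
            class = "skeleton_graph")
}

# step length in um between two 8-adjacent pixels
step_length <- function(r0, c0, r1, c1, ps) {
  ifelse(r0 != r1 & c0 != c1, sqrt(2) * ps, ps)
}

#' Trace branches and derive skeleton morphometry
#'
#' A branch is a maximal slab path between two terminals (endpoint or
#' junction cluster); its length accumulates `pixel_size_um` per orthogonal
#' step and `sqrt(2) * pixel_size_um` per diagonal step, terminal pixels
#' included. Isolated closed loops (slab-only cycles) are reported as
#' single branches of their cycle length. Populates the branch table and
#' the derived counts (`n_branches`, `n_junctions`, `n_endpoints`,
#' `total_branch_length_um`, `avg_branch_length_um`).
#'
#' @param graph A `skeleton_graph` from [classify_voxels()].
#' @param pixel_size_um Pixel size; defaults to the skeleton's calibration.
#' @return The `skeleton_graph` with `branches` (data.frame: end kinds and
#'   `length_um`) and the count/length summary filled in.
#' @export
extract_branches <- function(graph, pixel_size_um = pixel_size(graph$skeleton)) {
  m <- as_matrix(graph$skeleton)
  nr <- nrow(m)
  cls <- graph$class
  idx <- which(m)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  pos <- data.frame(idx = idx, r = rows, c = cols)
  # adjacency lookup by linear index
  in_skel <- m
  neigh <- function(r, c) {
    rr <- r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    cc <- c + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(m)
    rr <- rr[ok]; cc <- cc[ok]
    keep <- in_skel[cbind(rr, cc)]
    cbind(rr[keep], cc[keep])
  }
  visited <- array(FALSE, dim(m))      # slab pixels consumed by a branch
  ep_used <- array(FALSE, dim(m))      # endpoints already terminating a branch
  branches <- list()
  add_branch <- function(kind_a, kind_b, len, n_px) {
    branches[[length(branches) + 1L]] <<-
      data.frame(end_a = kind_a, end_b = kind_b, length_um = len,
                 n_pixels = n_px, stringsAsFactors = FALSE)
  }
  # walk from (r0,c0) through slabs starting toward (r1,c1); returns the
  # terminal pixel, accumulated length and pixel count
  walk <- function(r0, c0, r1, c1) {
    len <- step_length(r0, c0, r1, c1, pixel_size_um)
    n_px <- 2L
    pr <- r0; pc <- c0
    while (cls[r1, c1] == "slab") {
      visited[r1, c1] <<- TRUE
      nb <- neigh(r1, c1)
      nxt <- nb[!(nb[, 1] == pr & nb[, 2] == pc), , drop = FALSE]
      if (nrow(nxt) == 0L) break   # guarded: slab has 2 neighbors
      pr <- r1; pc <- c1
      r1 <- nxt[1, 1]; c1 <- nxt[1, 2]
      len <- len + step_length(pr, pc, r1, c1, pixel_size_um)
      n_px <- n_px + 1L
    }
    list(r = r1, c = c1, len = len, n_px = n_px)
  }
  term_kind <- function(r, c) if (cls[r, c] == "junction") "junction" else "endpoint"
  # 1) branches seeded at endpoints
  eps <- pos[cls[cbind(pos$r, pos$c)] == "endpoint", , drop = FALSE]
  for (i in seq_len(nrow(eps))) {
    r <- eps$r[i]; c <- eps$c[i]
    if (ep_used[r, c]) next
    ep_used[r, c] <- TRUE
    nb <- neigh(r, c)
    w <- walk(r, c, nb[1, 1], nb[1, 2])
    if (cls[w$r, w$c] == "endpoint") ep_used[w$r, w$c] <- TRUE
    add_branch("endpoint", term_kind(w$r, w$c), w$len, w$n_px)
  }
  # 2) branches seeded at junction-adjacent slabs
  jps <- pos[cls[cbind(pos$r, pos$c)] == "junction", , drop = FALSE]
  for (i in seq_len(nrow(jps))) {
    r <- jps$r[i]; c <- jps$c[i]
    nb <- neigh(r, c)
    for (k in seq_len(nrow(nb))) {
      sr <- nb[k, 1]; sc <- nb[k, 2]
      if (cls[sr, sc] != "slab" || visited[sr, sc]) next
      # a slab adjacent to two junction pixels of the same cluster would be
      # walked from both sides; visited marking dedupes
      w <- walk(r, c, sr, sc)
      if (cls[w$r, w$c] == "endpoint") {
        # already traced from the endpoint side
        if (ep_used[w$r, w$c]) next
        ep_used[w$r, w$c] <- TRUE
      }
      add_branch("junction", term_kind(w$r, w$c), w$len, w$n_px)
    }
  }
  # 3) leftover slab-only cycles
  slabs <- pos[cls[cbind(pos$r, pos$c)] == "slab", , drop = FALSE]
  for (i in seq_len(nrow(slabs))) {
    r <- slabs$r[i]; c <- slabs$c[i]
    if (visited[r, c]) next
    visited[r, c] <- TRUE
    nb <- neigh(r, c)
    len <- 0; n_px <- 1L
    pr <- r; pc <- c
    cr <- nb[1, 1]; cc <- nb[1, 2]
    len <- step_length(pr, pc, cr, cc, pixel_size_um)
    while (!(cr == r && cc == c)) {
      visited[cr, cc] <- TRUE
      n_px <- n_px + 1L
      nb2 <- neigh(cr, cc)
      nxt <- nb2[!(nb2[, 1] == pr & nb2[, 2] == pc), , drop = FALSE]
      if (nrow(nxt) == 0L) break
      pr <- cr; pc <- cc
      cr <- nxt[1, 1]; cc <- nxt[1, 2]
      len <- len + step_length(pr, pc, cr, cc, pixel_size_um)
    }
    add_branch("cycle", "cycle", len, n_px)
  }
  graph$branches <- if (length(branches)) do.call(rbind, branches)
  else data.frame(end_a = character(0), end_b = character(0),
                  length_um = numeric(0), n_pixels = integer(0))
  graph$n_branches <- nrow(graph$branches)
  graph$n_junctions <- graph$n_junction_clusters
  graph$total_branch_length_um <- sum(graph$branches$length_um)
  graph$avg_branch_length_um <- if (graph$n_branches > 0)
    graph$total_branch_length_um / graph$n_branches else 0
  graph
}

#' Count somata from the pre-expansion nuclei mask
#'
#' Automated replacement for manual multipoint counting: the number of
#' 8-connected components of the nuclei mask after small-object removal,
#' before expansion.
#'
#' @param nuclei_mask_pre_expansion A `binary_mask`.
#' @return Integer count.
#' @export
count_somata <- function(nuclei_mask_pre_expansion) {
  max(.label8(as_matrix(nuclei_mask_pre_expansion)))
}

#' Measure one acquisition end to end
#'
#' Composes the full workflow: (max projection if z-stacks are supplied)
#' -> nuclei/soma masks -> neurite mask -> skeletonization -> voxel
#' classification -> branch extraction -> soma counting, and returns one
#' morphometry row. A blank marker channel yields a zero-branch record with
#' average branch length reported as 0 (flagged via `avg_defined`).
#'
#' @param acq An `acquisition` (from [generate_acquisition()] or
#'   [read_acquisition()]). Fields `dapi_stack` / `map2_stack` (lists of
#'   planes), when present, are max-projected first.
#' @param params A [masking_params()] list.
#' @param image_id,group,replicate Metadata carried into the record.
#' @return A one-row data.frame (`morphometry_record`): `n_somata`,
#'   `n_branches`, `n_junctions`, `n_endpoints`, `total_branch_length_um`,
#'   `avg_branch_length_um`, `avg_defined`.
#' @export
measure_acquisition <- function(acq, params = masking_params(),
                                image_id = "img", group = NA_character_,
                                replicate = NA_integer_) {
  dapi <- if (!is.null(acq$dapi_stack)) max_project(acq$dapi_stack) else acq$dapi
  map2 <- if (!is.null(acq$map2_stack)) max_project(acq$map2_stack) else acq$map2
  check_same_shape(dapi, map2, "dapi and map2")
  nm <- build_nuclei_mask(dapi, params)
  neurite <- build_neurite_mask(map2, nm$soma, params)
  graph <- extract_branches(classify_voxels(skeletonize(neurite)))
  data.frame(image_id = image_id, group = group, replicate = replicate,
             n_somata = count_somata(nm$nuclei),
             n_branches = graph$n_branches,
             n_junctions = graph$n_junctions,
             n_endpoints = graph$n_endpoints,
             total_branch_length_um = graph$total_branch_length_um,
             avg_branch_length_um = graph$avg_branch_length_um,
             avg_defined = graph$n_branches > 0,
             stringsAsFactors = FALSE)
}

#' Measure every acquisition of a cohort
#'
#' @param cohort A `cohort` from [generate_group()], or any list whose
#'   elements have `acquisition`, `image_id`, `group`, `replicate`.
#' @param params A [masking_params()] list.
#' @return A data.frame with one `morphometry_record` row per acquisition.
#' @export
measure_cohort <- function(cohort, params = masking_params()) {
  rows <- lapply(cohort, function(e)
    measure_acquisition(e$acquisition, params, image_id = e$image_id,
                        group = e$group, replicate = e$replicate))
  do.call(rbind, rows)
}
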