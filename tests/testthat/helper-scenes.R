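# Shared fixtures, built in code.

# down-scaled generator parameters for fast scene tests: same calibration,
# smaller field and sparser population
small_params <- function(..., noise_model = "none") {
  generator_params(field_size_um = 60, n_cells = 3L,
                   nucleus_diameter_um_range = c(9, 12),
                   neurites_per_cell_range = c(1L, 2L),
                   mean_segment_len_um = 8,
                   noise_model = noise_model, ...)
}

# strip classes and calibration attributes for raw matrix comparison
as_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

img8 <- function(values, ps = 1) image2d(values, ps, bit_depth = 8L)

rand_img8 <- function(n, m = n, seed = 1) {
  set.seed(seed)
  img8(matrix(sample(0:255, n * m, replace = TRUE), n, m))
}

# binary mask from a logical matrix, unit calibration unless given
mask_of <- function(m, ps = 1) binary_mask(m, ps)

# random blob mask: thresholded smoothed noise
blob_mask <- function(n = 60, seed = 1, q = 0.75, ps = 1) {
  set.seed(seed)
  f <- gaussian_blur(image2d(matrix(runif(n * n), n, n) * 1000, ps), 2.5 * ps)
  mask_of(as.matrix(f) > stats::quantile(as.matrix(f), q), ps)
}

# independent recomputation of ground-truth metrics by a fresh walk over
# the exported node/edge lists (degree counting + polyline arithmetic)
recompute_truth <- function(truth) {
  deg <- integer(nrow(truth$nodes))
  total <- 0
  for (e in truth$edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
    p <- e$poly
    for (i in seq_len(nrow(p) - 1))
      total <- total + sqrt(sum((p[i + 1, ] - p[i, ])^2))
  }
  nb <- length(truth$edges)
  list(n_somata = nrow(truth$cell_centers),
       n_branches = nb,
       n_junctions = sum(deg >= 3L),
       n_endpoints = sum(deg == 1L & truth$nodes$kind != "soma-root"),
       total_branch_length_um = total,
       avg_branch_length_um = if (nb > 0) total / nb else 0)
}
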