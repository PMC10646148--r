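# Synthetic acquisition generator and its ground truth.

test_that("generation is deterministic for a fixed seed", {
  p <- small_params(seed = 123, noise_model = "poisson")
  a <- generate_acquisition(p)
  b <- generate_acquisition(p)
  expect_identical(as_matrix(a$acquisition$dapi), as_matrix(b$acquisition$dapi))
  expect_identical(as_matrix(a$acquisition$map2), as_matrix(b$acquisition$map2))
  expect_identical(a$truth$true_metrics, b$truth$true_metrics)
  c <- generate_acquisition(small_params(seed = 124, noise_model = "poisson"))
  expect_false(identical(as_matrix(a$acquisition$map2),
                         as_matrix(c$acquisition$map2)))
})

test_that("empty scenes contain background only and all-zero metrics", {
  p <- generator_params(field_size_um = 30, n_cells = 0L,
                        branching_prob = 0, noise_model = "none", seed = 1)
  g <- generate_acquisition(p)
  expect_true(all(as_matrix(g$acquisition$map2) == p$background_level))
  tm <- g$truth$true_metrics
  expect_identical(tm$n_somata, 0L)
  expect_identical(tm$n_branches, 0L)
  expect_identical(tm$n_junctions, 0L)
  expect_equal(tm$total_branch_length_um, 0)
})

test_that("a single unbranched neurite gives one branch, no junctions", {
  p <- generator_params(field_size_um = 80, n_cells = 1L,
                        neurites_per_cell_range = c(1L, 1L),
                        branching_prob = 0, mean_segment_len_um = 6,
                        noise_model = "none", seed = 21)
  g <- generate_acquisition(p)
  tm <- g$truth$true_metrics
  expect_identical(tm$n_branches, 1L)
  expect_identical(tm$n_junctions, 0L)
  expect_identical(tm$n_endpoints, 1L)
  # total length equals the drawn polyline length outside the clipped disk
  expect_equal(tm$total_branch_length_um,
               sum(sapply(g$truth$edges, function(e) {
                 p <- e$poly
                 sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                   p[-nrow(p), , drop = FALSE])^2)))
               })))
  expect_gt(tm$total_branch_length_um, 0)
})

test_that("ground truth is self-consistent under an independent graph walk", {
  for (s in c(2, 7, 31)) {
    g <- generate_acquisition(small_params(seed = s))
    tm <- g$truth$true_metrics
    rc <- recompute_truth(g$truth)
    expect_identical(tm$n_somata, rc$n_somata)
    expect_identical(tm$n_branches, rc$n_branches)
    expect_identical(tm$n_junctions, rc$n_junctions)
    expect_identical(tm$n_endpoints, rc$n_endpoints)
    expect_equal(tm$total_branch_length_um, rc$total_branch_length_um)
    expect_equal(tm$avg_branch_length_um, rc$avg_branch_length_um)
  }
})

test_that("every edge endpoint is a node and lengths are positive", {
  g <- generate_acquisition(small_params(seed = 17))
  ids <- g$truth$nodes$id
  for (e in g$truth$edges) {
    expect_true(e$from %in% ids && e$to %in% ids)
    p <- e$poly
    expect_gt(sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                p[-nrow(p), , drop = FALSE])^2))), 0)
  }
})

test_that("expected branch and junction counts increase with branching", {
  mean_counts <- function(bp, seeds) {
    tm <- sapply(seeds, function(s) {
      g <- generate_acquisition(small_params(branching_prob = bp, seed = s))
      c(g$truth$true_metrics$n_branches, g$truth$true_metrics$n_junctions)
    })
    rowMeans(tm)
  }
  lo <- mean_counts(0.05, 1:30)
  hi <- mean_counts(0.35, 1:30)
  expect_gt(hi[1], lo[1])
  expect_gt(hi[2], lo[2])
})

test_that("with no noise or PSF, marker signal stays inside the geometry", {
  p <- small_params(seed = 13, psf_sigma_um = 0)
  g <- generate_acquisition(p)
  m <- as_matrix(g$acquisition$map2)
  above <- which(m > p$background_level, arr.ind = TRUE)
  ps <- p$pixel_size_um
  cells <- g$truth$cell_centers
  ok <- logical(nrow(above))
  for (i in seq_len(nrow(above))) {
    x <- (above[i, 2] - 0.5) * ps; y <- (above[i, 1] - 0.5) * ps
    # inside a soma disk (+ half-pixel anti-aliasing rim)?
    if (any(sqrt((cells$x - x)^2 + (cells$y - y)^2) <= cells$r + ps)) {
      ok[i] <- TRUE
      next
    }
    # within the stamped width of any rendered segment?
    for (e in g$truth$tree_edges) {
      pl <- e$poly
      lim <- (e$width_px / 2 + 1) * ps
      for (k in seq_len(nrow(pl) - 1)) {
        a <- pl[k, ]; b <- pl[k + 1, ]
        d <- b - a; L2 <- sum(d^2)
        tt <- if (L2 > 0) min(max(((x - a[1]) * d[1] + (y - a[2]) * d[2]) / L2, 0), 1) else 0
        if (sqrt((x - a[1] - tt * d[1])^2 + (y - a[2] - tt * d[2])^2) <= lim) {
          ok[i] <- TRUE
          break
        }
      }
      if (ok[i]) break
    }
  }
  expect_true(all(ok))
})

test_that("cohorts have the stated cardinality and derived seeds", {
  wt <- small_params(seed = 5)
  ko <- small_params(branching_prob = 0.1, seed = 5)
  coh <- generate_group(wt, ko, n_images_per_group = 2L, n_replicates = 3L,
                        master_seed = 42L)
  expect_length(coh, 12L)
  groups <- vapply(coh, `[[`, "", "group")
  expect_identical(sum(groups == "WT"), 6L)
  expect_identical(sum(groups == "KO"), 6L)
  seeds <- vapply(coh, function(e) e$acquisition$provenance$seed, 0L)
  expect_identical(anyDuplicated(seeds), 0L)
  # reproducible from the master seed
  coh2 <- generate_group(wt, ko, 2L, 3L, master_seed = 42L)
  expect_identical(vapply(coh2, function(e) e$acquisition$provenance$seed, 0L),
                   seeds)
})

test_that("placement fails loudly when the field cannot hold the cells", {
  p <- generator_params(field_size_um = 25, n_cells = 12L,
                        nucleus_diameter_um_range = c(9, 12),
                        noise_model = "none", seed = 1)
  expect_error(generate_acquisition(p), "cannot hold|smaller than")
})

test_that("parameter invariants are enforced", {
  expect_error(generator_params(branching_prob = 1.4))
  expect_error(generator_params(neurite_width_px_range = c(1, 9)), "width")
  expect_error(generator_params(nucleus_diameter_um_range = c(12, 9)))
  expect_error(generator_params(pixel_size_um = 0))
})
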