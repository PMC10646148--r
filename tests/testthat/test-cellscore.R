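# Per-cell scoring: segmentation, intensity, double-positive fractions.

# deterministic scene: n disks on a dark background, optional marker images
disk_scene <- function(n_side = 200, centers, radius = 12, level = 10000,
                       bg = 200, ps = 0.207) {
  m <- matrix(0, n_side, n_side)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((1:n_side - centers[i, 1])^2,
                    (1:n_side - centers[i, 2])^2, "+"))
    m[d <= radius] <- level
  }
  image2d(m + bg, ps)
}

five_centers <- cbind(c(40, 40, 100, 160, 160), c(40, 160, 100, 40, 160))

test_that("cell segmentation finds each nucleus once, speckles excluded", {
  nuc <- disk_scene(centers = five_centers)
  regions <- segment_cells(nuc, scoring_params())
  expect_identical(nrow(regions$records), 5L)
  # speckles below the particle area are dropped
  m <- as_matrix(nuc)
  set.seed(6)
  m[cbind(sample(1:200, 30), sample(1:200, 30))] <- 10000
  regions2 <- segment_cells(image2d(m, 0.207), scoring_params())
  expect_identical(nrow(regions2$records), 5L)
  # centroids sit on the generating centers
  got <- regions2$records[order(regions2$records$centroid_row,
                                regions2$records$centroid_col), ]
  want <- five_centers[order(five_centers[, 1], five_centers[, 2]), ]
  expect_true(all(abs(got$centroid_row - want[, 1]) < 2))
  expect_true(all(abs(got$centroid_col - want[, 2]) < 2))
  # blank channel: empty region set
  expect_identical(nrow(segment_cells(image2d(matrix(5, 50, 50), 1))$records),
                   0L)
})

test_that("per-region mean intensities match a brute-force accumulation", {
  nuc <- disk_scene(centers = five_centers)
  regions <- segment_cells(nuc, scoring_params())
  cst <- image2d(matrix(77, 200, 200), 0.207)
  rec <- measure_intensity(regions, cst)
  expect_true(all(rec$mean_intensity == 77))
  set.seed(14)
  chan <- image2d(matrix(runif(200 * 200, 0, 4000), 200, 200), 0.207)
  rec <- measure_intensity(regions, chan)
  for (id in rec$cell_id) {
    px <- regions$labels == id
    expect_equal(rec$mean_intensity[rec$cell_id == id],
                 sum(as_matrix(chan)[px]) / sum(px))
  }
  # indicator region x 100
  ind <- image2d(matrix(0, 200, 200), 0.207)
  ind[regions$labels == 1L] <- 100
  rec <- measure_intensity(regions, ind)
  expect_equal(rec$mean_intensity[rec$cell_id == 1L], 100)
})

test_that("double-positive fractions recover the labeled ground truth", {
  nuc <- disk_scene(centers = five_centers)
  regions <- segment_cells(nuc, scoring_params())
  bright_in <- function(which_cells) {
    m <- matrix(0, 200, 200)
    for (i in which_cells) {
      d <- sqrt(outer((1:200 - five_centers[i, 1])^2,
                      (1:200 - five_centers[i, 2])^2, "+"))
      m[d <= 14] <- 8000
    }
    image2d(m + 100, 0.207)
  }
  # all cells positive in both channels
  res <- classify_double_positive(regions, bright_in(1:5), bright_in(1:5))
  expect_equal(res$fraction, 1)
  # 2 of the 5 cells positive in the second channel
  res <- classify_double_positive(regions, bright_in(1:5), bright_in(c(1, 4)))
  expect_equal(res$fraction, 2 / 5)
  expect_identical(sum(res$cells$double_positive), 2L)
  # fraction invariant to monotone rescaling of a two-valued channel
  ch <- bright_in(c(1, 2, 3))
  ch2 <- image2d(as_matrix(ch) * 3 + 50, 0.207)
  f1 <- classify_double_positive(regions, ch, bright_in(1:5))$fraction
  f2 <- classify_double_positive(regions, ch2, bright_in(1:5))$fraction
  expect_equal(f1, f2)
})

test_that("subsampled fractions converge to the population fraction", {
  # grid of well-separated nuclei
  grid <- as.matrix(expand.grid(seq(25, 375, by = 50), seq(25, 375, by = 50)))
  nuc <- disk_scene(n_side = 400, centers = grid, radius = 10)
  regions <- segment_cells(nuc, scoring_params())
  n <- nrow(regions$records)
  expect_identical(n, nrow(grid))
  pos <- grid[seq_len(n) %% 2 == 0, , drop = FALSE]   # half the cells
  mk <- function(centers) {
    m <- matrix(0, 400, 400)
    for (i in seq_len(nrow(centers))) {
      d <- sqrt(outer((1:400 - centers[i, 1])^2, (1:400 - centers[i, 2])^2, "+"))
      m[d <= 12] <- 9000
    }
    image2d(m + 100, 0.207)
  }
  full <- classify_double_positive(regions, mk(pos), mk(grid))
  sub_small <- classify_double_positive(regions, mk(pos), mk(grid),
                                        scoring_params(n_cells_per_group = 10,
                                                       n_groups = 40),
                                        subsample = TRUE, seed = 3)
  sub_big <- classify_double_positive(regions, mk(pos), mk(grid),
                                      scoring_params(n_cells_per_group = 50,
                                                     n_groups = 40),
                                      subsample = TRUE, seed = 3)
  err_small <- abs(mean(sub_small$group_fractions) - full$fraction)
  sd_small <- sd(sub_small$group_fractions)
  sd_big <- sd(sub_big$group_fractions)
  expect_lt(sd_big, sd_small)           # larger groups concentrate
  expect_lt(err_small, 0.15)
  expect_true(all(sub_small$group_fractions >= 0 &
                  sub_small$group_fractions <= 1))
})

test_that("scoring matches generator truth on a labeled synthetic scene", {
  g <- generate_acquisition(small_params(seed = 3))
  regions <- segment_cells(g$acquisition$dapi, scoring_params())
  expect_identical(nrow(regions$records), nrow(g$truth$cell_centers))
  # centroids within 2 px of the generator's cell centers
  ps <- g$acquisition$pixel_size_um
  for (i in seq_len(nrow(regions$records))) {
    dx <- (regions$records$centroid_col[i] - 0.5) * ps - g$truth$cell_centers$x
    dy <- (regions$records$centroid_row[i] - 0.5) * ps - g$truth$cell_centers$y
    expect_lt(min(sqrt(dx^2 + dy^2)), 2 * ps)
  }
})
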