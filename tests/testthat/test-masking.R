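# Filtering and the two-mask segmentation pipeline.

test_that("max projection is the per-pixel maximum across planes", {
  a <- img8(matrix(1:64, 8, 8))
  expect_equal(as_matrix(max_project(list(a))), as_matrix(a))
  b <- img8(matrix(1:64 + 10, 8, 8))
  expect_equal(as_matrix(max_project(list(a, b))), as_matrix(b))
  set.seed(2)
  planes <- lapply(1:3, function(i) img8(matrix(sample(0:255, 64, TRUE), 8, 8)))
  got <- as_matrix(max_project(planes))
  for (r in 1:8) for (c in 1:8)
    expect_identical(got[r, c],
                     max(planes[[1]][r, c], planes[[2]][r, c],
                         planes[[3]][r, c]))
  expect_error(max_project(list(a, img8(matrix(0, 4, 4)))), "shape")
})

test_that("contrast enhancement clips at sorted order statistics", {
  set.seed(8)
  v <- sample(0:255, 1000, replace = TRUE)
  img <- img8(matrix(v, 40, 25))
  out <- enhance_contrast(img, 0.01)
  s <- sort(v)
  lo <- s[5]; hi <- s[996]          # 0.5th / 99.5th order statistics
  expect_equal(as_matrix(out),
               matrix(round(pmin(pmax((v - lo) / (hi - lo) * 255, 0), 255)),
                      40, 25))
  # order preserved on non-clipped pixels
  keep <- v > lo & v < hi
  expect_true(all(diff(as.numeric(out)[keep][order(v[keep])]) >= 0))
  # full-range image with zero saturation: unchanged up to rounding
  w <- img8(matrix(c(0, 255, sample(0:255, 62, TRUE)), 8, 8))
  expect_equal(as_matrix(enhance_contrast(w, 0)), as_matrix(w))
  # constant image: unchanged, with a notice
  cst <- img8(matrix(9, 5, 5))
  expect_message(out <- enhance_contrast(cst, 0.01), "constant")
  expect_equal(as_matrix(out), as_matrix(cst))
})

test_that("gaussian blur preserves mean, mass and constancy", {
  cst <- image2d(matrix(42, 20, 20), 0.207)
  expect_equal(as_matrix(gaussian_blur(cst, 2)), as_matrix(cst),
               tolerance = 1e-10)
  # unit impulse: kernel sums to 1 and is radially symmetric
  imp <- image2d({m <- matrix(0, 41, 41); m[21, 21] <- 1; m}, 1)
  out <- as_matrix(gaussian_blur(imp, 3))
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_equal(out[21, 26], out[26, 21], tolerance = 1e-12)
  expect_equal(out[16, 21], out[21, 16], tolerance = 1e-12)
  # mean preserved within 0.1% on a random image (reflective boundaries)
  set.seed(5)
  img <- image2d(matrix(runif(64 * 64, 0, 1000), 64, 64), 0.207)
  expect_equal(mean(as_matrix(gaussian_blur(img, 2))), mean(as_matrix(img)),
               tolerance = 1e-3)
})

test_that("LoG filter: zero on constants, ridge-positive, matches 2-D kernel", {
  cst <- image2d(matrix(17, 16, 16), 1)
  expect_true(all(abs(as_matrix(log_filter(cst, 2))) < 1e-9))
  # single bright 1-px line: maximal response on the line
  m <- matrix(0, 21, 21); m[11, ] <- 100
  resp <- as_matrix(log_filter(image2d(m, 1), 1.5))
  expect_true(all(resp[11, 5:15] >= resp[9, 5:15]))
  expect_gt(min(resp[11, 5:15]), 0)
  expect_identical(unname(which.max(resp[, 11])), 11L)
  # direct 2-D convolution oracle on a random 16x16 image (interior pixels)
  set.seed(12)
  img <- image2d(matrix(runif(256, 0, 255), 16, 16), 1)
  s <- 1.2; r <- ceiling(4 * s)
  x <- (-r):r
  g <- exp(-x^2 / (2 * s^2)); g <- g / sum(g)
  d2g <- g * (x^2 - s^2) / s^4
  d2g <- d2g - mean(d2g)                    # zero-mean corrected
  K <- -(outer(d2g, g) + outer(g, d2g))     # LoG kernel, ridge-positive
  resp <- as_matrix(log_filter(img, s))
  for (rr in (r + 1):(16 - r)) for (cc in (r + 1):(16 - r)) {
    patch <- as_matrix(img)[rr + x, cc + x]
    expect_equal(resp[rr, cc], sum(K * patch), tolerance = 1e-9)
  }
})

test_that("small-component removal uses the equivalent-circle radius", {
  disk <- function(n, r, ctr = n / 2) {
    d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
    d <= r
  }
  big <- mask_of(disk(60, 25))
  expect_identical(as_matrix(remove_small_components(big, 20)),
                   as_matrix(big))
  sq <- matrix(FALSE, 30, 30); sq[10:14, 10:14] <- TRUE  # area 25, req ~2.8
  expect_identical(sum(remove_small_components(mask_of(sq), 20)), 0L)
  # random blob field vs brute-force per-component area filter
  for (s in 1:5) {
    msk <- blob_mask(50, seed = s, q = 0.8)
    kept <- remove_small_components(msk, 3)
    m <- as.matrix(msk)
    lab <- matrix(0L, nrow(m), ncol(m))
    nxt <- 0L
    for (cc in seq_len(ncol(m))) for (rr in seq_len(nrow(m))) {
      if (!m[rr, cc] || lab[rr, cc]) next
      nxt <- nxt + 1L
      todo <- list(c(rr, cc)); lab[rr, cc] <- nxt
      while (length(todo)) {
        p <- todo[[length(todo)]]; todo[[length(todo)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1] + dr; c2 <- p[2] + dc
          if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m) &&
              m[r2, c2] && !lab[r2, c2]) {
            lab[r2, c2] <- nxt
            todo[[length(todo) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
    areas <- tabulate(lab[lab > 0], nbins = nxt)
    want <- m
    for (k in seq_len(nxt))
      if (sqrt(areas[k] / pi) < 3) want[lab == k] <- FALSE
    expect_identical(as_matrix(kept), as_matrix(want))
  }
})

test_that("mask expansion is the exact Euclidean disk", {
  m <- matrix(FALSE, 21, 21); m[11, 11] <- TRUE
  out <- expand_mask(mask_of(m), 5)
  # discrete Euclidean disk of radius 5 contains 81 pixels
  d <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, "+"))
  expect_identical(as_matrix(out), d <= 5 + 1e-9)
  expect_identical(sum(out), sum(d <= 5))
  # identity at zero, monotone in the input
  expect_identical(as_matrix(expand_mask(mask_of(m), 0)), as_matrix(m))
  a <- blob_mask(40, seed = 2, q = 0.85)
  b <- mask_of(as.matrix(a) | as.matrix(blob_mask(40, seed = 3, q = 0.85)))
  ea <- expand_mask(a, 3); eb <- expand_mask(b, 3)
  expect_true(all(!as.logical(ea) | as.logical(eb)))
})

test_that("nuclei pipeline keeps nuclei, drops speckles, counts cells", {
  n <- 300
  m <- matrix(0, n, n)
  ctr <- cbind(c(60, 60, 220, 150, 240), c(60, 230, 60, 150, 240))
  for (i in 1:5) {
    d <- sqrt(outer((1:n - ctr[i, 1])^2, (1:n - ctr[i, 2])^2, "+"))
    m[d <= 25] <- 12000
  }
  set.seed(31)
  sp <- cbind(sample(1:n, 50, TRUE), sample(1:n, 50, TRUE))
  m[sp] <- 12000                      # 1-px speckles
  dapi <- image2d(m + 300, 0.207)
  nm <- build_nuclei_mask(dapi, masking_params())
  expect_identical(count_somata(nm$nuclei), 5L)
  # expanded soma mask is a superset of the nuclei mask
  expect_true(all(!as.logical(nm$nuclei) | as.logical(nm$soma)))
})

test_that("neurite mask is disjoint from the soma mask and empty on blanks", {
  g <- generate_acquisition(small_params(seed = 5))
  nm <- build_nuclei_mask(g$acquisition$dapi)
  msk <- build_neurite_mask(g$acquisition$map2, nm$soma)
  expect_false(any(as.logical(msk) & as.logical(nm$soma)))
  blank <- image2d(matrix(100, 64, 64), 0.207)
  soma <- mask_of(matrix(FALSE, 64, 64), 0.207)
  expect_message(out <- build_neurite_mask(blank, soma), "blank")
  expect_identical(sum(out), 0L)
})

test_that("rerunning the masking on identical input is bit-identical", {
  g <- generate_acquisition(small_params(seed = 9))
  nm1 <- build_nuclei_mask(g$acquisition$dapi)
  nm2 <- build_nuclei_mask(g$acquisition$dapi)
  expect_identical(as_matrix(nm1$soma), as_matrix(nm2$soma))
  m1 <- build_neurite_mask(g$acquisition$map2, nm1$soma)
  m2 <- build_neurite_mask(g$acquisition$map2, nm2$soma)
  expect_identical(as_matrix(m1), as_matrix(m2))
})
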