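# Morphometry: segmentation, thinning, geodesic path extraction and length.

# brute-force all-pairs chamfer geodesic (Floyd-Warshall) on a toy skeleton;
# independent of the igraph-based implementation
bf_geodesic_diameter <- function(skel) {
  idx <- which(skel)
  n <- length(idx)
  nr <- nrow(skel)
  rc <- cbind(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dr <- abs(rc[i, 1] - rc[j, 1])
      dc <- abs(rc[i, 2] - rc[j, 2])
      if (i != j && dr <= 1 && dc <= 1) {
        D[i, j] <- if (dr + dc == 2) sqrt(2) else 1
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  max(D[is.finite(D)])
}

mk_mask <- function(nr, nc, coords) {
  m <- matrix(FALSE, nr, nc)
  m[coords] <- TRUE
  m
}

test_that("chamfer path length is exact on toy paths", {
  horiz <- tibble::tibble(row = rep(5L, 11), col = 1:11)
  expect_identical(path_length(horiz, px_size_um = 1), 10)

  diag <- tibble::tibble(row = 1:11, col = 1:11)
  expect_equal(path_length(diag, px_size_um = 1), 10 * sqrt(2))

  # 5 orthogonal + 5 diagonal steps at 2 um/px
  stair <- tibble::tibble(row = c(1, 1, 1, 1, 1, 1, 2, 3, 4, 5, 6),
                          col = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11))
  expect_equal(path_length(stair, px_size_um = 2), 10 + 10 * sqrt(2))

  single <- tibble::tibble(row = 1L, col = 1L)
  expect_identical(path_length(single, px_size_um = 1), 0)
  expect_error(path_length(tibble::tibble(row = c(1, 5), col = c(1, 1))),
               "8-adjacent")
})

test_that("longest path recovers lines and resolves T-junction spurs", {
  line <- mk_mask(5, 13, cbind(3, 2:12))
  p <- longest_path(line)
  expect_equal(nrow(p), 11)
  expect_equal(path_length(p, 1), 10)

  # T shape: horizontal bar of 21 px (two 10-px arms), vertical spur 4 px
  tmask <- mk_mask(10, 25, rbind(cbind(2, 2:22), cbind(3:6, 12)))
  tp <- longest_path(tmask)
  expect_equal(nrow(tp), 21)
  expect_equal(path_length(tp, 1), 20)
  expect_equal(path_length(tp, 1), bf_geodesic_diameter(tmask))

  # consecutive pixels 8-adjacent, no repeats
  expect_true(all(abs(diff(tp$row)) <= 1 & abs(diff(tp$col)) <= 1))
  expect_false(any(duplicated(tp[, c("row", "col")])))

  single <- mk_mask(3, 3, cbind(2, 2))
  sp <- longest_path(single)
  expect_equal(nrow(sp), 1)
  expect_identical(path_length(sp, 1), 0)
})

test_that("longest path equals the brute-force geodesic on random toys", {
  for (s in 1:5) {
    skel <- withr::with_seed(s, {
      m <- mk_mask(9, 9, cbind(5, 2:8))
      # random walk appendage
      r <- 5L
      c <- 5L
      for (i in 1:6) {
        r <- max(1L, min(9L, r + sample(c(-1L, 0L, 1L), 1)))
        c <- max(1L, min(9L, c + sample(c(-1L, 0L, 1L), 1)))
        m[r, c] <- TRUE
      }
      m
    })
    p <- longest_path(skel)
    expect_equal(path_length(p, 1), bf_geodesic_diameter(skel),
                 tolerance = 1e-12)
  }
})

test_that("segmentation thresholds correctly and detects polarity", {
  # already-binary image, fixed threshold 0.5: identity
  bin <- matrix(0, 20, 20)
  bin[8:12, 4:16] <- 1
  img <- worm_image(bin, 1)
  mask <- segment_worm(img, method = "fixed", fixed_threshold = 0.5)
  expect_identical(unname(mask == TRUE), bin == 1)

  # constant image: no object
  expect_error(segment_worm(worm_image(matrix(0.3, 10, 10), 1)),
               "no object found")

  # dark worm on bright background found by auto polarity
  inv <- worm_image(1 - bin * 0.8, 1)
  mask2 <- segment_worm(inv)
  expect_identical(unname(mask2 == TRUE), bin == 1)

  # synthetic worm: IoU >= 0.9 against generator truth
  w <- gen_worm_image(220, seed = 11)
  m <- segment_worm(w$image)
  iou <- sum(m & w$truth$mask) / sum(m | w$truth$mask)
  expect_gte(iou, 0.9)
})

test_that("largest_component removes debris and flags ties", {
  # speck is 1 px = 2.5% of the 40-px worm: removed without a flag
  m <- mk_mask(20, 45, rbind(cbind(5, 3:42), cbind(15, 44)))
  out <- largest_component(m)
  expect_equal(sum(out), 40)
  expect_false(out[15, 44])
  expect_false(attr(out, "qc_multiple_components"))

  one <- mk_mask(10, 10, cbind(5, 2:8))
  expect_identical(which(largest_component(one)), which(one))

  # two equal components: keep the first in scan order, flag
  tie <- mk_mask(10, 20, rbind(cbind(2, 2:6), cbind(8, 10:14)))
  kept <- largest_component(tie)
  expect_true(kept[2, 2])
  expect_false(kept[8, 10])
  expect_true(attr(kept, "qc_multiple_components"))

  expect_error(largest_component(matrix(FALSE, 3, 3)), "empty")
})

test_that("thinning yields a one-pixel midline for bars and dots for disks", {
  bar <- mk_mask(7, 15, as.matrix(expand.grid(3:5, 3:13)))
  sk <- skeletonize(bar)
  # skeleton concentrated on the midline row, spanning most of the bar
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] == 4))
  expect_gte(sum(sk), 8)

  disk <- mk_mask(21, 21, which(
    (row(matrix(0, 21, 21)) - 11)^2 + (col(matrix(0, 21, 21)) - 11)^2 <= 49,
    arr.ind = TRUE))
  skd <- skeletonize(disk)
  expect_lte(sum(skd), 8)
  expect_error(skeletonize(matrix(FALSE, 5, 5)), "empty")
})

test_that("measured length is accurate, unit-linear and rotation-stable", {
  w <- gen_worm_image(210, amplitude_um = 0, noise_sd = 0.02, seed = 21)
  m <- measure_worm_length(w$image)
  expect_lt(abs(m$length_um - 210) / 210, 0.03)
  expect_false(m$qc_multiple_components)

  # doubling the pixel size exactly doubles the measured length
  img2 <- worm_image(w$image$pixels, px_size_um = 2)
  m2 <- measure_worm_length(img2)
  expect_equal(m2$length_um, 2 * m$length_um)

  # 90-degree rotation changes the estimate by < 0.5%
  rot <- worm_image(t(w$image$pixels)[ncol(w$image$pixels):1, ], 1)
  mr <- measure_worm_length(rot)
  expect_lt(abs(mr$length_um - m$length_um) / m$length_um, 0.005)

  # measured length >= straight-line endpoint distance of the path
  curved <- gen_worm_image(240, amplitude_um = 20, seed = 8)
  mask <- largest_component(segment_worm(curved$image))
  p <- longest_path(skeletonize(mask), 1)
  chord <- sqrt((p$row[1] - p$row[nrow(p)])^2 +
                  (p$col[1] - p$col[nrow(p)])^2)
  expect_gte(path_length(p, 1), chord)

  expect_error(measure_worm_length(worm_image(matrix(0.5, 10, 10), 1)),
               "no object")
})

test_that("raw chamfer output is available and bit-exact", {
  w <- gen_worm_image(210, amplitude_um = 0, noise_sd = 0, seed = 3)
  m_raw <- measure_worm_length(w$image, smooth_path = FALSE,
                               extend_tips = FALSE)
  mask <- largest_component(segment_worm(w$image))
  op <- wormdev:::binary_open3(mask)
  p <- longest_path(skeletonize(largest_component(op)), 1)
  expect_identical(m_raw$length_um, path_length(p, 1))
})

test_that("coiled shapes raise the self-overlap flag", {
  ring <- mk_mask(30, 30, which(
    abs(sqrt((row(matrix(0, 30, 30)) - 15)^2 +
               (col(matrix(0, 30, 30)) - 15)^2) - 10) <= 2.2,
    arr.ind = TRUE))
  p <- longest_path(skeletonize(ring))
  expect_true(attr(p, "qc_self_overlap_suspected"))
})
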