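test_that("2-means on a two-color image recovers the exact partition", {
  img <- two_tone_image()
  mask <- kmeans_pixel_mask(rgb_to_lab(img), segmentation_params())
  truth <- matrix(FALSE, 40, 40); truth[12:29, 12:29] <- TRUE
  # with exactly two distinct colors the optimal 2-means is the exact
  # two-value partition; the border rule must pick the interior color
  expect_identical(mask, truth)
})

test_that("degenerate single-color images give an empty mask, not a crash", {
  flat <- array(77, c(20, 20, 3))
  expect_warning(mask <- kmeans_pixel_mask(flat), "degenerate")
  expect_true(all(!mask))
})

test_that("zero-noise scene mask covers cell interiors and no background", {
  sc <- generate_scene(scene_spec(width = 200, height = 200, n_cells = 10,
                                  noise_sd = 0, class_sd = 0,
                                  background_sd = 0, seed = 6))
  mask <- kmeans_pixel_mask(rgb_to_lab(sc$image), segmentation_params())
  fg <- sc$truth$label_map > 0
  expect_true(all(mask[fg]))     # superset of interiors
  expect_true(all(!mask[!fg]))   # no background pixel
})

test_that("Otsu matches the exhaustive between-class-variance sweep", {
  g <- matrix(c(rep(50, 900), rep(200, 100)), 100, 10)
  res <- otsu_mask(g)
  expect_gt(res$threshold, 50); expect_lt(res$threshold, 200)
  expect_equal(sum(res$mask), 100)        # fewer-on-border side is foreground
  expect_true(all(g[res$mask] == 200))

  set.seed(11)
  for (i in 1:5) {
    r <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_equal(floor(otsu_mask(r)$threshold), brute_force_otsu(r))
  }
  expect_error(otsu_mask(matrix(5, 4, 4)), "no threshold")
})

test_that("the conservative mask is the pixelwise intersection", {
  set.seed(2)
  a <- matrix(runif(30 * 20) > 0.5, 30, 20)
  b <- matrix(runif(30 * 20) > 0.5, 30, 20)
  expect_identical(conservative_mask(a, a), a)            # idempotent
  expect_true(all(!conservative_mask(a, !a)))             # disjoint -> empty
  expect_identical(conservative_mask(a, b), naive_and(a, b))
  expect_error(conservative_mask(a, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("watershed labels a disk whole and splits merged disks", {
  d <- disk_mask(30, 30, 15, 15, 9)
  w1 <- watershed_cells(d, segmentation_params())
  expect_equal(max(w1), 1L)
  expect_identical(w1 > 0, d)

  merged <- disk_mask(40, 60, 20, 22, 10) | disk_mask(40, 60, 20, 38, 10)
  w2 <- watershed_cells(merged, segmentation_params())
  expect_equal(max(w2), 2L)
  expect_identical(w2 > 0, merged)        # union of labels = mask
  # the split runs near the neck midline (column 30)
  cols <- ((which(w2 == 1L) - 1L) %/% 40) + 1L
  expect_lt(max(cols), 34)

  empty <- watershed_cells(matrix(FALSE, 10, 10), segmentation_params())
  expect_true(all(empty == 0L))
})

test_that("filtering removes small and border regions and relabels in scan order", {
  p50 <- segmentation_params(min_cell_area = 50)
  small <- matrix(0L, 20, 20); small[5:6, 5:9] <- 1L       # 10 px
  expect_true(all(filter_cells(small, p50) == 0L))

  border <- matrix(0L, 20, 20); border[1:10, 5:14] <- 1L   # touches row 1
  expect_true(all(filter_cells(border, p50) == 0L))
  keep <- filter_cells(border, segmentation_params(min_cell_area = 50,
                                                   border_policy = "keep"))
  expect_equal(max(keep), 1L)

  # survivors {2, 5, 9} -> {1, 2, 3} by reading order of first pixel
  m <- matrix(0L, 30, 40)
  m[2:9, 30:37] <- 9L    # first pixel: row 2
  m[12:19, 3:10] <- 5L   # row 12
  m[22:29, 20:27] <- 2L  # row 22
  f <- filter_cells(m, segmentation_params(min_cell_area = 10,
                                           border_policy = "keep"))
  expect_equal(unique(f[m == 9L]), 1L)
  expect_equal(unique(f[m == 5L]), 2L)
  expect_equal(unique(f[m == 2L]), 3L)
})

test_that("raising min_cell_area never increases the surviving count", {
  sc <- generate_scene(scene_spec(width = 250, height = 250, n_cells = 15,
                                  radius_range = c(4, 12), seed = 13))
  labels <- watershed_cells(sc$truth$label_map > 0, segmentation_params())
  counts <- vapply(c(0, 30, 60, 120, 300), function(a)
    max(filter_cells(labels, segmentation_params(min_cell_area = a,
                                                 border_policy = "keep"))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the segmentation pipeline recovers the synthetic truth", {
  sc <- generate_scene(scene_spec(width = 300, height = 300, n_cells = 20,
                                  seed = 21))
  labels <- segment_cells(sc$image)
  m <- match_instances(labels, sc$truth$label_map, iou_min = 0.5)
  expect_gte(m$recall, 0.95)
  # conservative property: every instance pixel is on in BOTH paths
  fg <- labels > 0
  expect_true(all(attr(labels, "kmeans_mask")[fg]))
  expect_true(all(attr(labels, "otsu_mask")[fg]))
  # determinism
  labels2 <- segment_cells(sc$image)
  expect_identical(unclass(labels)[], unclass(labels2)[])
})

test_that("a blank scene segments to zero cells with warnings", {
  blank <- color_image(array(200, c(80, 80, 3)))
  labels <- suppressWarnings(segment_cells(blank))
  expect_equal(max(labels), 0L)
})
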