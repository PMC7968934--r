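test_that("empty scene is pure background with an empty label map", {
  sc <- generate_scene(scene_spec(width = 60, height = 50, n_cells = 0,
                                  background_sd = 0, seed = 1))
  expect_equal(dim(sc$image), c(50, 60, 3))
  expect_true(all(sc$truth$label_map == 0L))
  expect_equal(nrow(sc$truth$cells), 0L)
  expect_true(all(sc$image[, , 1] == 200))
})

test_that("a single noiseless cell has the analytic ellipse area", {
  sc <- generate_scene(scene_spec(width = 100, height = 100, n_cells = 1,
                                  radius_range = c(10, 10), noise_sd = 0,
                                  class_sd = 0, background_sd = 0, seed = 5))
  lm <- sc$truth$label_map
  expect_equal(max(lm), 1L)
  area <- sum(lm == 1L)
  # semi-major is fixed at 10; the axis ratio is drawn in [0.6, 1], so the
  # analytic pi*a*b lies in [0.6, 1]*pi*100 — and the rasterized area must
  # sit within 10% of the pi*a*b implied by the region's own second
  # moments (for a uniform ellipse the covariance eigenvalues are a^2/4
  # and b^2/4)
  expect_gt(area, 0.9 * 0.6 * pi * 100)
  expect_lt(area, 1.1 * pi * 100)
  idx <- which(lm == 1L, arr.ind = TRUE)
  ev <- eigen(stats::cov(idx), only.values = TRUE)$values
  analytic <- pi * prod(2 * sqrt(ev))
  expect_equal(area, analytic, tolerance = 0.1)
})

test_that("identical specs regenerate bit-identical scenes", {
  spec <- scene_spec(width = 120, height = 120, n_cells = 8, seed = 42)
  a <- generate_scene(spec); b <- generate_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$label_map, b$truth$label_map)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("label values are contiguous, connected, and in bounds", {
  sc <- generate_scene(scene_spec(width = 150, height = 130, n_cells = 10,
                                  seed = 9))
  lm <- sc$truth$label_map
  K <- nrow(sc$truth$cells)
  expect_setequal(setdiff(unique(as.vector(lm)), 0L), seq_len(K))
  cc <- EBImage::imageData(EBImage::bwlabel(lm > 0))
  for (k in seq_len(K))  # each label maps into exactly one component
    expect_length(unique(cc[lm == k]), 1L)
  expect_equal(sc$truth$cells$area, tabulate(lm[lm > 0], K))
})

test_that("interior colors converge to the class mean as area grows", {
  spec <- scene_spec(width = 200, height = 200, n_cells = 4,
                     classes = "only", class_means = matrix(c(110, 90, 140),
                       1, dimnames = list("only", NULL)),
                     class_sd = 0, noise_sd = 5,
                     radius_range = c(14, 16), seed = 3)
  sc <- generate_scene(spec)
  for (k in seq_len(nrow(sc$truth$cells))) {
    idx <- sc$truth$label_map == k
    area <- sum(idx)
    for (ch in 1:3) {
      expect_lt(abs(mean(sc$image[, , ch][idx]) - spec$class_means[1, ch]),
                3 * 5 / sqrt(area) + 0.5)  # +0.5 for 8-bit rounding
    }
  }
})

test_that("a new seed changes pixels but not the cell roster", {
  s1 <- generate_scene(scene_spec(width = 200, height = 200, n_cells = 6,
                                  seed = 1))
  s2 <- generate_scene(scene_spec(width = 200, height = 200, n_cells = 6,
                                  seed = 2))
  expect_false(identical(s1$image, s2$image))
  expect_equal(nrow(s1$truth$cells), nrow(s2$truth$cells))
  expect_setequal(unique(s1$truth$cells$class), unique(s2$truth$cells$class))
})

test_that("impossible placement yields a partial scene, not a hang", {
  expect_warning(
    sc <- generate_scene(scene_spec(width = 60, height = 60, n_cells = 50,
                                    radius_range = c(10, 10), seed = 1)),
    "placed")
  expect_false(sc$truth$placement_complete)
  expect_lt(nrow(sc$truth$cells), 50)
})

test_that("instance matching is greedy one-to-one by IoU", {
  sc <- generate_scene(scene_spec(width = 120, height = 120, n_cells = 6,
                                  seed = 8))
  lm <- sc$truth$label_map
  self <- match_instances(lm, lm, iou_min = 0.5)
  expect_equal(self$n_matched, max(lm))
  expect_true(all(self$pairs$iou == 1))
  expect_equal(self$n_missed, 0L)

  none <- match_instances(matrix(0L, 120, 120), lm)
  expect_equal(none$n_matched, 0L)
  expect_equal(none$n_missed, max(lm))

  # two 10x10 squares offset by 5 px: IoU = 50 / 150 = 1/3
  a <- matrix(0L, 30, 30); a[6:15, 6:15] <- 1L
  b <- matrix(0L, 30, 30); b[11:20, 6:15] <- 1L
  m <- match_instances(a, b, iou_min = 0.5)
  expect_equal(m$pairs$iou, 1 / 3)
  expect_equal(m$n_matched, 0L)
  expect_equal(m$n_missed, 1L)
  expect_equal(m$n_spurious, 1L)
  expect_equal(match_instances(a, b, iou_min = 0.3)$n_matched, 1L)

  expect_error(match_instances(a, matrix(0L, 10, 10)), "dimensions")
})
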