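#' Specify a synthetic stained-cell scene
#'
#' Describes a field of sparse, roughly elliptical cells over a near-uniform
#' bright background, emulating bright-field images of dye-stained cultures:
#' the background is bright gray and each class of cells carries a distinct
#' interior color (distinct R:G:B ratios), the signal the colorimetric
#' features encode.  Identical specs (same seed) regenerate bit-identical
#' scenes.
#'
#' @param width,height image size in pixels.
#' @param n_cells number of cells to attempt to place.
#' @param classes character vector of class names.
#' @param class_means matrix (classes x 3) of mean interior RGB in
#'   `[0, 255]`, rownames = classes.  The default palette gives three
#'   well-separated yellowish/greenish/bluish profiles on a bright
#'   background, the contrast regime of stained bright-field cultures.
#' @param class_sd per-channel sd of the cell-to-cell base color draw.
#' @param radius_range length-2 range of the semi-major axis, pixels (>= 2).
#' @param background_mean,background_sd background RGB mean and pixel sd.
#' @param noise_sd i.i.d. per-pixel, per-channel Gaussian noise sd added to
#'   cell interiors (clipped to `[0, 255]`).
#' @param min_sep_frac overlap policy: minimum center distance between two
#'   cells as a fraction of the sum of their semi-major axes.  1 forbids
#'   overlap; values < 1 allow touching/merged cells (useful for stressing
#'   the watershed split).
#' @param shading_slope optional linear illumination gradient: intensity
#'   offset per pixel along x, applied to all channels (0 = flat field).
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return an object of class `"scene_spec"`.
#' @seealso [generate_scene()]
#' @export
scene_spec <- function(width = 400L, height = 400L, n_cells = 40L,
                       classes = c("lineA", "lineB", "lineC"),
                       class_means = NULL,
                       class_sd = 6,
                       radius_range = c(8, 16),
                       background_mean = c(200, 200, 200),
                       background_sd = 3,
                       noise_sd = 8,
                       min_sep_frac = 1.0,
                       shading_slope = 0,
                       seed = 1L) {
  if (is.null(class_means)) {
    palette <- matrix(c(
      120, 110,  60,   # olive-yellow (acidic end of the dye)
       95, 130,  95,   # green        (neutral)
       75,  90, 125),  # blue-gray    (alkaline end)
      ncol = 3, byrow = TRUE)
    default_names <- c("lineA", "lineB", "lineC")
    rows <- if (all(classes %in% default_names)) match(classes, default_names)
            else rep_len(seq_len(3), length(classes))
    class_means <- palette[rows, , drop = FALSE]
    rownames(class_means) <- classes
  }
  class_means <- as.matrix(class_means)
  if (is.null(rownames(class_means))) rownames(class_means) <- classes
  stopifnot(
    width >= 1, height >= 1, n_cells >= 0,
    nrow(class_means) == length(classes), ncol(class_means) == 3,
    all(class_means >= 0 & class_means <= 255),
    class_sd >= 0, background_sd >= 0, noise_sd >= 0,
    length(radius_range) == 2, all(radius_range >= 2),
    all(background_mean >= 0 & background_mean <= 255))
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_cells = as.integer(n_cells), classes = as.character(classes),
    class_means = class_means, class_sd = class_sd,
    radius_range = sort(as.numeric(radius_range)),
    background_mean = as.numeric(background_mean),
    background_sd = background_sd, noise_sd = noise_sd,
    min_sep_frac = min_sep_frac, shading_slope = shading_slope,
    seed = as.integer(seed)), class = "scene_spec")
}

#' Generate a synthetic scene with ground truth
#'
#' Places `n_cells` ellipses (axis ratio uniform in `[0.6, 1]`, random
#' orientation) by rejection sampling under the spec's overlap policy, each
#' attempted at most 100 times; fills each with its class color model plus
#' pixel noise on the background model, and returns the 8-bit image together
#' with the ground-truth instance map, per-cell classes, centroids and
#' areas.  Cells are placed wholly inside the field.  If placement gives up
#' before all cells fit, the scene is returned partial with
#' `truth$placement_complete = FALSE` and a warning — never an infinite
#' loop.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` (a [color_image()]) and `truth`, a
#'   list with `label_map` (integer matrix, 0 = background, labels
#'   `1..n_placed` contiguous), `cells` (data.frame: cell_id, class,
#'   centroid_x, centroid_y, area) and `placement_complete`.
#' @examples
#' sc <- generate_scene(scene_spec(width = 120, height = 120, n_cells = 4,
#'                                 seed = 7))
#' table(sc$truth$cells$class)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, function() .generate_scene_impl(spec))
}

.generate_scene_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  n <- spec$n_cells
  # draw per-cell geometry + class up front so count/classes are stable
  # across placement outcomes for a given seed
  cls <- if (n > 0) sample(spec$classes, n, replace = TRUE) else character()
  rad <- runif(n, spec$radius_range[1], spec$radius_range[2])
  ratio <- runif(n, 0.6, 1.0)
  theta <- runif(n, 0, pi)

  cx <- cy <- numeric(0)  # accepted centers
  keep <- logical(n)
  for (i in seq_len(n)) {
    a <- rad[i]
    lo_x <- a + 1; hi_x <- w - a; lo_y <- a + 1; hi_y <- h - a
    if (hi_x <= lo_x || hi_y <= lo_y) next  # cell larger than field
    for (attempt in seq_len(100L)) {
      x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
      if (length(cx)) {
        min_d <- spec$min_sep_frac * (rad[keep][seq_along(cx)] + a)
        if (any(sqrt((cx - x)^2 + (cy - y)^2) < min_d)) next
      }
      cx <- c(cx, x); cy <- c(cy, y); keep[i] <- TRUE
      break
    }
  }
  placed <- which(keep)
  if (length(placed) < n)
    warning(sprintf("placed %d of %d cells before giving up", length(placed), n))

  labels <- matrix(0L, h, w)
  col_grid <- matrix(rep(seq_len(w), each = h), h, w)
  row_grid <- matrix(rep(seq_len(h), times = w), h, w)
  for (j in seq_along(placed)) {
    i <- placed[j]
    a <- rad[i]; b <- rad[i] * ratio[i]
    ct <- cos(theta[i]); st <- sin(theta[i])
    # bounding box then exact ellipse test
    r0 <- max(1L, floor(cy[j] - a)); r1 <- min(h, ceiling(cy[j] + a))
    c0 <- max(1L, floor(cx[j] - a)); c1 <- min(w, ceiling(cx[j] + a))
    rr <- row_grid[r0:r1, c0:c1] - cy[j]
    cc <- col_grid[r0:r1, c0:c1] - cx[j]
    u <- cc * ct + rr * st
    v <- -cc * st + rr * ct
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- labels[r0:r1, c0:c1]
    sub[inside] <- j
    labels[r0:r1, c0:c1] <- sub
  }

  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- spec$background_mean[ch] +
      rnorm(h * w, 0, spec$background_sd)
  }
  base <- matrix(0, length(placed), 3)
  for (j in seq_along(placed)) {
    mu <- spec$class_means[cls[placed[j]], ]
    base[j, ] <- rnorm(3, mu, spec$class_sd)
  }
  idx <- which(labels > 0)
  if (length(idx)) {
    lab_at <- labels[idx]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- base[lab_at, ch] + rnorm(length(idx), 0, spec$noise_sd)
      img[, , ch] <- plane
    }
  }
  if (spec$shading_slope != 0)
    img <- img + array(rep((col_grid - 1) * spec$shading_slope, 3),
                       dim = c(h, w, 3))
  img <- pmin(pmax(round(img), 0), 255)

  cells <- data.frame(
    cell_id = seq_along(placed),
    class = if (length(placed)) cls[placed] else character(),
    centroid_x = vapply(seq_along(placed),
                        function(j) mean(col_grid[labels == j]), numeric(1)),
    centroid_y = vapply(seq_along(placed),
                        function(j) mean(row_grid[labels == j]), numeric(1)),
    area = if (length(placed)) tabulate(labels[labels > 0], length(placed))
           else integer(),
    stringsAsFactors = FALSE)
  list(image = color_image(img),
       truth = list(label_map = labels, cells = cells,
                    placement_complete = length(placed) == n))
}

#' Match predicted cell instances to ground truth by IoU
#'
#' Greedy one-to-one matching: all (predicted, truth) label pairs with
#' positive overlap are ranked by descending intersection-over-union and
#' accepted in order, each label used at most once; pairs with IoU >=
#' `iou_min` count as detected.
#'
#' @param predicted,truth integer label maps of identical dimensions
#'   (0 = background).
#' @param iou_min minimum IoU for a pair to count as a detection.
#' @return list: `pairs` (data.frame truth_label, pred_label, iou, matched),
#'   `n_matched`, `n_missed`, `n_spurious`, `recall`.
#' @export
match_instances <- function(predicted, truth, iou_min = 0.5) {
  if (!identical(dim(predicted), dim(truth)))
    stop("predicted and truth label maps must have identical dimensions")
  np <- max(predicted, 0L); nt <- max(truth, 0L)
  area_p <- tabulate(predicted[predicted > 0], np)
  area_t <- tabulate(truth[truth > 0], nt)
  both <- predicted > 0 & truth > 0
  if (any(both)) {
    key <- paste(truth[both], predicted[both])
    ov <- table(key)
    parts <- do.call(rbind, strsplit(names(ov), " ", fixed = TRUE))
    tl <- as.integer(parts[, 1]); pl <- as.integer(parts[, 2])
    inter <- as.integer(ov)
    iou <- inter / (area_t[tl] + area_p[pl] - inter)
    ord <- order(-iou, tl, pl)
    tl <- tl[ord]; pl <- pl[ord]; iou <- iou[ord]
    used_t <- logical(nt); used_p <- logical(np)
    sel <- logical(length(tl))
    for (i in seq_along(tl)) {
      if (!used_t[tl[i]] && !used_p[pl[i]]) {
        sel[i] <- TRUE; used_t[tl[i]] <- TRUE; used_p[pl[i]] <- TRUE
      }
    }
    pairs <- data.frame(truth_label = tl[sel], pred_label = pl[sel],
                        iou = iou[sel])
    pairs$matched <- pairs$iou >= iou_min
  } else {
    pairs <- data.frame(truth_label = integer(), pred_label = integer(),
                        iou = numeric(), matched = logical())
  }
  n_matched <- sum(pairs$matched)
  list(pairs = pairs,
       n_matched = n_matched,
       n_missed = nt - n_matched,
       n_spurious = np - n_matched,
       recall = if (nt > 0) n_matched / nt else NA_real_)
}
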