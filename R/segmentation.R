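#' Segmentation parameters
#'
#' Tunables for the dual-path segmentation.  The dual-path design is
#' conservative by construction: a pixel enters the cell mask only when the
#' CIELAB k-means path and the grayscale Otsu path agree.
#'
#' @param kmeans_k number of pixel clusters (>= 2; the cell/background
#'   dichotomy makes 2 the documented default).
#' @param kmeans_seed seed for k-means++ initialization; fixed so masks are
#'   reproducible.
#' @param kmeans_restarts number of seeded restarts; the run with the lowest
#'   within-cluster sum of squares wins.
#' @param min_cell_area minimum region area (px) kept by [filter_cells()].
#' @param border_policy `"drop"` removes regions touching the image border
#'   (partial cells), `"keep"` retains them.
#' @param smooth_sigma Gaussian sigma (px) applied to the distance transform
#'   before marker detection; suppresses spurious maxima from pixelation.
#' @param min_marker_distance minimum Euclidean distance (px) between
#'   watershed markers; merges near-duplicate maxima within one cell.
#' @return an object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(kmeans_k = 2L, kmeans_seed = 1L,
                                kmeans_restarts = 10L,
                                min_cell_area = 50L,
                                border_policy = c("drop", "keep"),
                                smooth_sigma = 1.0,
                                min_marker_distance = 5) {
  border_policy <- match.arg(border_policy)
  stopifnot(kmeans_k >= 2, kmeans_restarts >= 1, min_cell_area >= 0,
            smooth_sigma >= 0, min_marker_distance >= 0)
  structure(list(kmeans_k = as.integer(kmeans_k),
                 kmeans_seed = as.integer(kmeans_seed),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 min_cell_area = as.integer(min_cell_area),
                 border_policy = border_policy,
                 smooth_sigma = smooth_sigma,
                 min_marker_distance = min_marker_distance),
            class = "segmentation_params")
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding)
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) { centers[j + 1L, ] <- x[sample.int(n, 1L), ]; next }
    pick <- sample.int(n, 1L, prob = d2)
    centers[j + 1L, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1L, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

.border_index <- function(h, w) {
  m <- matrix(FALSE, h, w)
  m[1, ] <- TRUE; m[h, ] <- TRUE; m[, 1] <- TRUE; m[, w] <- TRUE
  which(m)
}

#' Foreground mask by k-means pixel clustering in CIELAB
#'
#' Clusters the per-pixel (L, a, b) vectors with Lloyd's algorithm
#' (k-means++ seeding, best of `kmeans_restarts` runs by within-cluster sum
#' of squares).  Because nothing in the clustering says which cluster is
#' "cell", the background cluster is identified as the one occupying the
#' larger share of the image border (ties go to the larger cluster) —
#' robust for sparse cells in a uniform field; all other clusters are
#' foreground.
#'
#' A single-color (degenerate) image yields an all-background mask with a
#' warning rather than an error.
#'
#' @param lab a `lab_image` from [rgb_to_lab()] (any h x w x 3 array works).
#' @param params [segmentation_params()].
#' @return logical `height x width` matrix, TRUE = cell pixel.
#' @export
kmeans_pixel_mask <- function(lab, params = segmentation_params()) {
  d <- dim(lab)
  if (length(d) != 3L || d[3] != 3L) stop("lab must be a h x w x 3 array")
  x <- matrix(as.numeric(lab), ncol = 3L)
  if (all(x[, 1] == x[1, 1] & x[, 2] == x[1, 2] & x[, 3] == x[1, 3])) {
    warning("degenerate clustering: image has a single color; empty mask")
    return(matrix(FALSE, d[1], d[2]))
  }
  k <- params$kmeans_k
  fit <- with_seed(params$kmeans_seed, function() {
    best <- NULL
    for (r in seq_len(params$kmeans_restarts)) {
      centers <- .kmeanspp_centers(x, k)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    best
  })
  if (is.null(fit)) {
    warning("degenerate clustering: k-means failed on every restart")
    return(matrix(FALSE, d[1], d[2]))
  }
  cl <- fit$cluster
  border <- .border_index(d[1], d[2])
  border_counts <- tabulate(cl[border], k)
  bg <- which(border_counts == max(border_counts))
  if (length(bg) > 1L) bg <- bg[which.max(fit$size[bg])]  # tie: larger cluster
  matrix(cl != bg, d[1], d[2])
}

#' Otsu threshold and foreground mask
#'
#' Builds a 256-bin histogram (unit bins on the 8-bit scale, matching 8-bit
#' camera output) and picks the threshold maximizing the between-class
#' variance.  Polarity — which side of the threshold is "cell" — is decided
#' by border occupancy, as for the k-means path: the side contributing fewer
#' border pixels is foreground (dark cells on a bright field by default, but
#' the rule adapts to inverted contrast).
#'
#' @param gray a `height x width` numeric matrix on the `[0, 255]` scale.
#' @return list with `mask` (logical matrix) and `threshold` (numeric; the
#'   cut sits at the upper edge of the last low bin).
#' @export
otsu_mask <- function(gray) {
  if (!is.matrix(gray)) stop("gray must be a matrix")
  if (min(gray) == max(gray)) stop("no threshold exists: constant image")
  bins <- pmin(pmax(floor(gray), 0), 255)
  h <- as.numeric(tabulate(as.integer(bins) + 1L, 256L))
  n <- sum(h)
  lv <- as.numeric(0:255)
  w0 <- cumsum(h)                      # pixels in bins 0..t
  m0 <- cumsum(h * lv)                 # first moment of bins 0..t
  mt <- m0[256]
  w0t <- w0[1:255]; m0t <- m0[1:255]   # candidate cuts t = 0..254
  w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mt * w0t[valid] / n - m0t[valid])^2 /
    (w0t[valid] / n * w1t[valid])
  t_star <- which.max(bcv) - 1L        # threshold between bin t* and t*+1
  low <- bins <= t_star
  border <- .border_index(nrow(gray), ncol(gray))
  low_border <- sum(low[border])
  fg_is_low <- low_border < (length(border) - low_border)
  mask <- if (fg_is_low) low else !low
  list(mask = mask, threshold = t_star + 0.5)
}

#' Conservative mask: pixelwise intersection of two foreground estimates
#'
#' A pixel is a cell pixel only if both independent paths classified it as
#' one.
#'
#' @param a,b logical masks of identical dimensions.
#' @return logical matrix `a & b`.
#' @export
conservative_mask <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical dimensions")
  a & b
}

# local maxima (>= all 8 neighbours, strictly positive) of a matrix
.local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  is_max <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (m >= pad[(2:(h + 1L)) + di, (2:(w + 1L)) + dj])
  }
  is_max & m > 0
}

#' Split a binary mask into cell instances with marker-controlled watershed
#'
#' Markers are the local maxima of the Gaussian-smoothed Euclidean distance
#' transform of the mask, thinned so no two markers lie closer than
#' `min_marker_distance` (maxima are ranked by distance value; lower-ranked
#' maxima within the exclusion radius of an accepted one are merged into
#' it).  The watershed then floods the negated (unsmoothed) distance
#' transform restricted to the mask, so basins split at the distance-ridge
#' between touching cells.  Mask components left without a marker by the
#' thinning are labelled as whole components, so every mask pixel receives
#' exactly one positive label.
#'
#' @param mask logical matrix (TRUE = cell pixel).
#' @param params [segmentation_params()].
#' @return integer label map (0 = background, labels contiguous `1..K`).
#' @export
watershed_cells <- function(mask, params = segmentation_params()) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dist <- EBImage::imageData(EBImage::distmap(mask * 1))
  sm <- if (params$smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(dist, sigma = params$smooth_sigma))
  else dist
  cand <- which(.local_maxima(sm) & mask)
  if (!length(cand)) cand <- which(sm == max(sm[mask]) & mask)[1]
  h <- nrow(mask)
  ci <- ((cand - 1L) %% h) + 1L
  cj <- ((cand - 1L) %/% h) + 1L
  ord <- order(-sm[cand], cand)
  keep_i <- keep_j <- numeric(0); keep_idx <- integer(0)
  for (q in ord) {
    if (length(keep_i) &&
        any((keep_i - ci[q])^2 + (keep_j - cj[q])^2 <
            params$min_marker_distance^2)) next
    keep_i <- c(keep_i, ci[q]); keep_j <- c(keep_j, cj[q])
    keep_idx <- c(keep_idx, cand[q])
  }
  markers <- matrix(0L, h, ncol(mask))
  markers[keep_idx] <- seq_along(keep_idx)
  labels <- .ws_flood(-dist, markers, mask)
  # orphan components (marker thinned away): label them whole
  orphan <- mask & labels == 0L
  if (any(orphan)) {
    extra <- EBImage::imageData(EBImage::bwlabel(orphan * 1))
    labels[orphan] <- max(labels) + as.integer(extra[orphan])
  }
  .relabel_scan_order(labels)
}

# relabel positive regions 1..K by reading order (left-to-right within
# top-to-bottom rows) of each region's first pixel
.relabel_scan_order <- function(labels) {
  pos <- which(labels > 0L)
  if (!length(pos)) return(matrix(0L, nrow(labels), ncol(labels)))
  h <- nrow(labels)
  ri <- ((pos - 1L) %% h) + 1L
  cj <- ((pos - 1L) %/% h) + 1L
  reading <- (ri - 1) * ncol(labels) + (cj - 1)
  first <- tapply(reading, labels[pos], min)
  old_ids <- as.integer(names(first))
  new_of <- integer(max(old_ids))
  new_of[old_ids[order(first)]] <- seq_along(old_ids)
  out <- labels
  out[pos] <- new_of[labels[pos]]
  out
}

#' Filter cell instances by size and border contact
#'
#' Removes regions smaller than `min_cell_area`; under
#' `border_policy = "drop"` also removes regions touching the image border
#' (partial cells whose features would be biased).  Survivors are relabelled
#' `1..K` in reading order of each region's first pixel.
#'
#' @param labels integer label map.
#' @param params [segmentation_params()].
#' @return filtered, relabelled label map.
#' @export
filter_cells <- function(labels, params = segmentation_params()) {
  stopifnot(is.matrix(labels))
  K <- max(labels, 0L)
  if (K == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  area <- tabulate(labels[labels > 0L], K)
  drop <- area < params$min_cell_area
  if (params$border_policy == "drop") {
    b <- labels[.border_index(nrow(labels), ncol(labels))]
    drop[unique(b[b > 0L])] <- TRUE
  }
  out <- labels
  out[out > 0L & drop[pmax(out, 1L)]] <- 0L
  .relabel_scan_order(out)
}

#' Segment single cells from a color bright-field image
#'
#' The full instance-segmentation pipeline: CIELAB conversion and k-means
#' pixel clustering in one path, grayscale conversion and Otsu thresholding
#' in the other; intersection of the two foreground estimates
#' (conservative mask); marker-controlled watershed to split touching
#' cells; then area/border filtering.  Deterministic given
#' `params$kmeans_seed`.  A blank (single-color) image segments to an empty
#' map with warnings rather than failing.
#'
#' @param img a [color_image()].
#' @param params [segmentation_params()].
#' @return integer label map with attributes `kmeans_mask`, `otsu_mask`,
#'   `otsu_threshold` (the intermediate products, for auditing).
#' @examples
#' sc <- generate_scene(scene_spec(width = 150, height = 150, n_cells = 5,
#'                                 seed = 2))
#' labels <- segment_cells(sc$image)
#' max(labels)  # cells found
#' @export
segment_cells <- function(img, params = segmentation_params()) {
  img <- assert_color_image(img)
  lab <- rgb_to_lab(img)
  gray <- rgb_to_gray(img)
  km <- kmeans_pixel_mask(lab, params)
  ot <- tryCatch(otsu_mask(gray), error = function(e) {
    warning(conditionMessage(e))
    list(mask = matrix(FALSE, nrow(gray), ncol(gray)), threshold = NA_real_)
  })
  mask <- conservative_mask(km, ot$mask)
  labels <- watershed_cells(mask, params)
  labels <- filter_cells(labels, params)
  attr(labels, "kmeans_mask") <- km
  attr(labels, "otsu_mask") <- ot$mask
  attr(labels, "otsu_threshold") <- ot$threshold
  labels
}
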