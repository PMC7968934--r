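#' Canonical colorimetric feature names
#'
#' The 16 per-cell features are the four intensity statistics — total,
#' mean, median, standard deviation — of the four channels: red, green,
#' blue, and the luminance (gray) channel recomputed from RGB with the same
#' Rec. 709 weights the segmentation uses, so the whole table depends only
#' on the stored RGB raster.
#'
#' @param feature_set `"all"` (16 features), `"rgb"` (the 12 color-channel
#'   features) or `"gray"` (the 4 luminance features).
#' @return character vector of column names.
#' @export
feature_columns <- function(feature_set = c("all", "rgb", "gray")) {
  feature_set <- match.arg(feature_set)
  channels <- switch(feature_set,
                     all = c("red", "green", "blue", "gray"),
                     rgb = c("red", "green", "blue"),
                     gray = "gray")
  as.vector(t(outer(channels, c("total", "mean", "median", "std"),
                    function(ch, s) paste(s, ch, sep = "_"))))
}

# population standard deviation (divisor N)
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract per-cell colorimetric features
#'
#' For every labelled cell, computes the total (sum), arithmetic mean,
#' median (midpoint-averaged for even pixel counts) and population standard
#' deviation (divisor N) of each of the four channels — 16 colorimetric
#' features per cell — plus bookkeeping columns (area, centroid).  The
#' choice of the population rather than sample standard deviation is a
#' fixed, recorded convention; classification is invariant to it up to a
#' constant factor.
#'
#' @param img a [color_image()].
#' @param labels integer label map from [segment_cells()] (same raster
#'   dimensions; labels `1..K`, no empty labels).
#' @param image_id identifier stored with every row.
#' @param class_label optional class for all cells (length 1) or per cell
#'   (length K).
#' @return a `FeatureTable` data.frame: image_id, cell_id, class, area,
#'   centroid_x, centroid_y, then the 16 columns of [feature_columns()].
#' @examples
#' img <- color_image(array(rep(c(100, 50, 25), each = 4),
#'                          dim = c(2, 2, 3)))
#' labels <- matrix(1L, 2, 2)
#' extract_features(img, labels)[, c("total_red", "mean_blue")]
#' @export
extract_features <- function(img, labels, image_id = "image",
                             class_label = NULL) {
  img <- assert_color_image(img)
  if (!identical(dim(img)[1:2], dim(labels)))
    stop("image and label map dimensions differ")
  K <- max(labels, 0L)
  chans <- list(red = img[, , 1], green = img[, , 2], blue = img[, , 3],
                gray = rgb_to_gray(img))
  if (!is.null(class_label)) {
    if (!length(class_label) %in% c(1L, K))
      stop("class_label must have length 1 or one entry per cell")
    class_label <- rep_len(as.character(class_label), max(K, 1L))
  }
  h <- nrow(labels)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (!length(idx)) stop(sprintf("label %d has zero pixels", k))
    stats16 <- unlist(lapply(chans, function(ch) {
      v <- ch[idx]
      c(total = sum(v), mean = mean(v), median = stats::median(v),
        std = .pop_sd(v))
    }))
    names(stats16) <- feature_columns("all")
    rows[[k]] <- data.frame(
      image_id = image_id, cell_id = k,
      class = if (is.null(class_label)) NA_character_ else class_label[k],
      area = length(idx),
      centroid_x = mean(((idx - 1L) %/% h) + 1L),
      centroid_y = mean(((idx - 1L) %% h) + 1L),
      t(stats16), stringsAsFactors = FALSE)
  }
  out <- if (K > 0) do.call(rbind, rows) else
    cbind(data.frame(image_id = character(), cell_id = integer(),
                     class = character(), area = integer(),
                     centroid_x = numeric(), centroid_y = numeric()),
          as.data.frame(matrix(numeric(), 0, 16,
                               dimnames = list(NULL, feature_columns()))))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Per-cell blue fraction
#'
#' The fraction of the blue signal relative to the total color signal,
#' computed per cell as the ratio of channel medians:
#' `median_blue / (median_red + median_green + median_blue)`.  For a
#' blue-shifting pH dye this tracks intracellular alkalinity.  Cells with a
#' zero denominator (all-black) are returned as `NA` and flagged; group
#' summaries exclude them.
#'
#' @param table a `FeatureTable` from [extract_features()].
#' @return numeric vector of fractions in `[0, 1]` (NA where undefined),
#'   with attribute `excluded` giving the flagged row indices.
#' @export
blue_fraction <- function(table) {
  need <- c("median_red", "median_green", "median_blue")
  if (!all(need %in% names(table)))
    stop("table lacks the three color medians")
  den <- table$median_red + table$median_green + table$median_blue
  frac <- ifelse(den > 0, table$median_blue / den, NA_real_)
  structure(frac, excluded = which(den <= 0))
}

#' Summarize a group's blue fraction
#'
#' Mean of the per-cell fractions with a 95\% t-interval half-width.
#'
#' @param frac numeric vector of per-cell fractions (NAs dropped).
#' @return list: `n`, `mean`, `ci_halfwidth`.
#' @export
group_blue_fraction <- function(frac) {
  frac <- frac[!is.na(frac)]
  n <- length(frac)
  if (n < 2) stop("need at least 2 cells")
  list(n = n, mean = mean(frac),
       ci_halfwidth = stats::qt(0.975, n - 1) * stats::sd(frac) / sqrt(n))
}

#' Compare the blue fraction between two cell groups
#'
#' With equal group sizes and `paired = TRUE`, a paired t-test on the
#' within-pair differences; otherwise a two-sample Welch t-test (the
#' documented fallback when the pairing unit is unavailable, e.g. unequal
#' cell counts per line).  Two degenerate paired cases are handled by
#' convention rather than error: all differences exactly zero reports
#' `t = 0, p = 1`; nonzero constant differences (zero variance) report an
#' infinite t with `p = 0` and `degenerate = TRUE`.
#'
#' @param x,y per-cell blue fractions of the two groups (n >= 2 each; NAs
#'   dropped).
#' @param paired pair observations by position (requires equal lengths).
#' @param alpha significance threshold, default 0.05.
#' @return object of class `"blue_fraction_test"`: group summaries,
#'   `statistic`, `p_value`, `significant`, `method`, `degenerate`.
#' @export
compare_blue <- function(x, y, paired = FALSE, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  degenerate <- FALSE
  if (paired) {
    if (length(x) != length(y)) stop("paired comparison needs equal sizes")
    d <- x - y
    if (all(d == 0)) {
      stat <- 0; p <- 1; method <- "paired t-test"; degenerate <- TRUE
    } else if (stats::sd(d) == 0) {
      stat <- sign(mean(d)) * Inf; p <- 0
      method <- "paired t-test"; degenerate <- TRUE
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value; method <- tt$method
    }
  } else {
    tt <- stats::t.test(x, y)  # Welch
    stat <- unname(tt$statistic); p <- tt$p.value; method <- tt$method
  }
  structure(list(
    group1 = group_blue_fraction(x), group2 = group_blue_fraction(y),
    statistic = stat, p_value = p, significant = p < alpha,
    alpha = alpha, method = method, degenerate = degenerate),
    class = "blue_fraction_test")
}

#' @export
print.blue_fraction_test <- function(x, ...) {
  cat("Blue-fraction comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  group 1: mean %.4f (n = %d, 95%% CI +/- %.4f)\n",
              x$group1$mean, x$group1$n, x$group1$ci_halfwidth))
  cat(sprintf("  group 2: mean %.4f (n = %d, 95%% CI +/- %.4f)\n",
              x$group2$mean, x$group2$n, x$group2$ci_halfwidth))
  cat(sprintf("  t = %.3f, p = %.3g%s%s\n", x$statistic, x$p_value,
              if (x$significant) " (significant)" else "",
              if (x$degenerate) " [degenerate case]" else ""))
  invisible(x)
}
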