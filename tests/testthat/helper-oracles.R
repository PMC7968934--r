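# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive: every oracle recomputes its quantity from the
# definition, not through the package's code paths.

# exhaustive Otsu: try every cut t in 0..254 on unit bins and maximize the
# between-class variance computed from the definition
brute_force_otsu <- function(gray) {
  bins <- pmin(pmax(floor(gray), 0), 255)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- bins[bins <= t]; hi <- bins[bins > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(bins); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# pixelwise AND by explicit double loop
naive_and <- function(a, b) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    out[i, j] <- a[i, j] && b[i, j]
  out
}

# binary confusion scores straight from the printed formulas,
# treating class 1 (first row) as positive
naive_binary_scores <- function(cm) {
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  f1 <- 2 * (rec * prec) / (rec + prec)
  if (is.nan(f1)) f1 <- 0  # 0/0 at the no-true-positive corner: take 0
  list(CA = (tp + tn) / (tp + fp + fn + tn),
       precision = prec, recall = rec, F1 = f1)
}

# two-sided permutation p-value for a difference in means
perm_test_p <- function(x, y, n_perm = 10000, seed = 1) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y); nx <- length(x)
  hits <- withr::with_seed(seed, {
    h <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nx)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) h <- h + 1L
    }
    h
  })
  (hits + 1) / (n_perm + 1)
}

# flat two-color image: background color fills a frame (including the whole
# border), cell color fills the interior block
two_tone_image <- function(size = 40, inner = 12:29,
                           bg = c(210, 210, 210), fg = c(90, 120, 60)) {
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], size, size)
    plane[inner, inner] <- fg[ch]
    img[, , ch] <- plane
  }
  color_image(img)
}

# filled disk mask
disk_mask <- function(h, w, ci, cj, r) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- TRUE
  m
}

# well-separated two-class Gaussian feature matrix
separable_features <- function(n_per_class = 60, p = 16, gap = 10, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  x[seq_len(n_per_class), seq_len(4)] <-
    x[seq_len(n_per_class), seq_len(4)] + gap
  list(x = x, y = rep(c("a", "b"), each = n_per_class))
}

# tiny feature table with the canonical columns filled from given medians
table_from_medians <- function(med) {
  ft <- as.data.frame(matrix(0, nrow(med), 16,
                             dimnames = list(NULL, feature_columns())))
  ft$median_red <- med[, 1]; ft$median_green <- med[, 2]
  ft$median_blue <- med[, 3]
  cbind(data.frame(image_id = "m", cell_id = seq_len(nrow(med)),
                   class = NA_character_, area = 1,
                   centroid_x = 0, centroid_y = 0), ft)
}
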