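test_that("PCA selection honors the cumulative-variance contract", {
  # rank-1 data -> a single component
  set.seed(1)
  base <- rnorm(50)
  x1 <- outer(base, c(1, 2, -1, 0.5))
  expect_equal(select_pcs(x1)$k, 1L)

  # isotropic 6-D Gaussian: every PC explains ~1/6, so 5 components cannot
  # reach 99%
  x6 <- matrix(rnorm(2000 * 6), 2000, 6)
  expect_equal(select_pcs(x6, 0.99)$k, 6L)

  # boundary property against a dense eigendecomposition oracle
  for (s in 1:3) {
    set.seed(s)
    n <- 80; p <- 10
    x <- matrix(rnorm(n * p), n, p) %*% diag(exp(seq(0, -3, length = p)))
    sel <- select_pcs(x, 0.99)
    z <- scale(x)
    ev <- sort(eigen(stats::cov(z), only.values = TRUE)$values,
               decreasing = TRUE)
    cum <- cumsum(ev) / sum(ev)
    expect_gte(cum[sel$k], 0.99)
    if (sel$k > 1) expect_lt(cum[sel$k - 1], 0.99)
  }

  # constant columns dropped with a warning
  xc <- cbind(matrix(rnorm(40 * 3), 40, 3), 7)
  expect_warning(sel <- select_pcs(xc), "constant")
  expect_lte(sel$k, 3L)
})

test_that("projection transfers to new data consistently", {
  set.seed(2)
  x <- matrix(rnorm(60 * 5), 60, 5)
  sel <- select_pcs(x)
  expect_equal(predict(sel, x), sel$scores)
})

test_that("confusion scores reproduce the printed formulas", {
  perfect <- score_confusion(diag(c(50, 50)))
  expect_equal(perfect$CA, 1); expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1); expect_equal(perfect$F1, 1)

  cm <- matrix(c(40, 20, 10, 30), 2)  # rows = true: [[40,10],[20,30]]
  sc <- score_confusion(cm)
  expect_equal(sc$CA, 0.7)
  expect_equal(sc$per_class$precision[1], 40 / 60, tolerance = 1e-12)
  expect_equal(sc$per_class$recall[1], 40 / 50)
  expect_equal(sc$per_class$F1[1],
               2 * (0.8 * 40 / 60) / (0.8 + 40 / 60), tolerance = 1e-12)

  # weighted averages equal a brute-force per-class loop
  set.seed(5)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    m <- matrix(sample(0:30, K * K, TRUE), K)
    if (any(rowSums(m) == 0) || sum(m) == 0) next
    got <- suppressWarnings(score_confusion(m))
    expect_equal(got$CA, sum(diag(m)) / sum(m))
    N <- sum(m); accs <- precs <- recs <- f1s <- wts <- numeric(0)
    for (k in seq_len(K)) {
      tp <- m[k, k]; fp <- sum(m[, k]) - tp; fn <- sum(m[k, ]) - tp
      pr <- tp / (tp + fp); rc <- tp / (tp + fn)
      wts <- c(wts, sum(m[k, ])); precs <- c(precs, pr); recs <- c(recs, rc)
    }
    ok <- !is.nan(precs)
    expect_equal(got$precision, sum((precs * wts)[ok]) / sum(wts[ok]))
    expect_equal(got$recall, sum(recs * wts) / sum(wts))
  }
})

test_that("ROC/AUC matches enumeration and an independent library", {
  # perfectly separating scores
  p <- cbind(a = c(.9, .8, .2, .1), b = c(.1, .2, .8, .9))
  r <- roc_auc(p, c("a", "a", "b", "b"))
  expect_equal(r$auc, 1)

  # one inversion: labels (1,1,0,0), scores (.9,.4,.6,.1) -> AUC 0.75
  p2 <- cbind(pos = c(.9, .4, .6, .1), neg = 1 - c(.9, .4, .6, .1))
  r2 <- roc_auc(p2, c("pos", "pos", "neg", "neg"))
  expect_equal(r2$per_class$pos$auc, 0.75)

  # random scores vs pROC on the same data
  set.seed(9)
  y <- sample(c("x", "y"), 80, TRUE)
  s <- runif(80)
  probs <- cbind(x = s, y = 1 - s)
  ours <- roc_auc(probs, y)$per_class$x$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("y", "x"), quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)

  expect_error(roc_auc(probs, rep("x", 80)), "two classes")
})

test_that("cross-validation is perfect on separable classes and deterministic", {
  d <- separable_features(30)
  rep1 <- cross_validate(d$x, d$y, models = model_specs(c("knn", "logistic")),
                         folds = 5, seed = 3)
  expect_equal(rep1$scores$CA[1], 1.0)
  expect_equal(rep1$scores,
               cross_validate(d$x, d$y,
                              models = model_specs(c("knn", "logistic")),
                              folds = 5, seed = 3)$scores)
  expect_true(all(diff(rep1$scores$CA) <= 0))  # sorted by CA desc
  expect_length(rep1$pca_components_used, 5L)
})

test_that("a class smaller than the fold count is reported by name", {
  x <- matrix(rnorm(24 * 4), 24, 4)
  y <- c(rep("big", 20), rep("tiny", 4))
  expect_error(cross_validate(x, y, models = model_specs("knn"), folds = 10,
                              seed = 1),
               "tiny")
})

test_that("per-fold PCA does not leak test-fold information", {
  set.seed(10)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6)
  y <- rep(c("a", "b"), each = n / 2)
  x2 <- x
  x2[1, ] <- x2[1, ] + 50  # corrupt one (test-fold) row's features
  args <- list(models = model_specs("knn"), folds = 2, seed = 4)
  r1 <- do.call(cross_validate, c(list(x, y), args))
  r2 <- do.call(cross_validate, c(list(x2, y), args))
  # labels (hence folds) are unchanged; rows sharing row 1's fold are
  # predicted by a model and transform fit without row 1, so their pooled
  # probabilities must be bit-identical; rows in the other fold may change
  same <- vapply(seq_len(n),
                 function(i) identical(r1$probs[i, ], r2$probs[i, ]),
                 logical(1))
  expect_gte(sum(same[-1]), n / 2 - 1)
})

test_that("in-silico co-culture splits are disjoint, balanced, and scorable", {
  d <- separable_features(60)
  mk <- function(rows, cls) {
    ft <- as.data.frame(d$x[rows, ])
    names(ft) <- feature_columns()
    cbind(data.frame(image_id = cls, cell_id = seq_along(rows),
                     class = cls, area = 100,
                     centroid_x = 0, centroid_y = 0), ft)
  }
  tabs <- list(a = mk(1:60, "a"), b = mk(61:120, "b"))
  sp <- insilico_coculture(tabs, n_per_class = 25, seed = 5)
  expect_equal(nrow(sp$validation), 50L)
  expect_equal(as.numeric(table(sp$validation$class)), c(25, 25))
  key <- function(t) paste(t$image_id, t$cell_id)
  expect_length(intersect(key(sp$train), key(sp$validation)), 0L)

  expect_error(insilico_coculture(tabs, n_per_class = 100), "exceeds")

  cc <- coculture_validate(tabs, models = model_specs("logistic"),
                           n_per_class = 25, seed = 5)
  expect_equal(cc$scores$CA[1], 1.0)  # separable classes

  # marginal resampling preserves sizes and stays in-distribution per column
  spm <- insilico_coculture(tabs, n_per_class = 25, seed = 5,
                            marginal_resample = TRUE)
  expect_equal(nrow(spm$validation), 50L)
  expect_true(all(spm$validation$total_red %in% c(tabs$a$total_red,
                                                  tabs$b$total_red)))
})
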