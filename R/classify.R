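# helpers -------------------------------------------------------------------

# extract the numeric feature matrix from a FeatureTable or matrix
.feature_matrix <- function(x, feature_set = "all") {
  if (is.data.frame(x)) {
    cols <- feature_columns(feature_set)
    missing_cols <- setdiff(cols, names(x))
    if (length(missing_cols))
      stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
    as.matrix(x[, cols])
  } else as.matrix(x)
}

# standardization fitted on train, applied to test; constant columns
# dropped with a warning (they carry no variance for PCA)
.fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  keep <- sdev > 0
  if (!all(keep))
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  list(mu = mu[keep], sd = sdev[keep], keep = keep)
}
.apply_standardizer <- function(st, x)
  sweep(sweep(x[, st$keep, drop = FALSE], 2L, st$mu, "-"), 2L, st$sd, "/")

#' Select principal components to a cumulative explained-variance target
#'
#' Features are standardized (zero mean, unit variance per column; constant
#' columns dropped with a warning), then projected on the smallest number
#' of principal components whose cumulative explained-variance ratio
#' reaches `variance_target` (default 99\%).
#'
#' @param x a `FeatureTable` or numeric matrix (rows = cells).
#' @param variance_target cumulative explained-variance ratio in (0, 1].
#' @param feature_set which feature columns to use when `x` is a table.
#' @return list of class `"pca_projection"`: `scores` (n x k), `k`,
#'   `explained` (per-component ratios), plus the fitted transform, reusable
#'   on new data via `predict()`.
#' @export
select_pcs <- function(x, variance_target = 0.99, feature_set = "all") {
  m <- .feature_matrix(x, feature_set)
  if (nrow(m) < 2) stop("need at least 2 rows")
  st <- .fit_standardizer(m)
  z <- .apply_standardizer(st, m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(ratio)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE], k = k,
                 explained = ratio, rotation = pc$rotation,
                 standardizer = st, variance_target = variance_target),
            class = "pca_projection")
}

#' @export
predict.pca_projection <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else .feature_matrix(newdata)
  z <- .apply_standardizer(object$standardizer, m)
  (z %*% object$rotation)[, seq_len(object$k), drop = FALSE]
}

# stratified fold assignment: within each class, shuffled then dealt
# round-robin, so fold class proportions match the data
.stratified_folds <- function(y, folds) {
  y <- as.factor(y)
  small <- names(which(table(y) < folds))
  if (length(small))
    stop("class with fewer members than folds: ",
         paste(small, collapse = ", "))
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Scores from a confusion matrix
#'
#' Per class, one-vs-rest TP/FP/FN/TN are plugged into
#' `accuracy = (TP + TN) / (TP + FP + FN + TN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2 (recall x precision) / (recall + precision)`.  Multiclass
#' precision/recall/F1 aggregate by class-size weighted average (classes
#' with an undefined score — no predictions of that class — are excluded
#' from the average with a warning); CA is the overall
#' `trace / total`, which in the binary case reduces to the printed
#' accuracy formula exactly.
#'
#' @param cm K x K integer matrix, rows = true class, columns = predicted.
#' @return list: `CA`, `precision`, `recall`, `F1`, `per_class` data.frame.
#' @export
score_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) stop("non-empty square matrix required")
  N <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- N - tp - fp - fn
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- 2 * rec * prec / (rec + prec)
  f1[is.nan(f1)] <- 0      # precision and recall both 0
  wt <- rowSums(cm)
  ok_p <- !is.nan(prec)
  ok_r <- !is.nan(rec)
  if (!all(ok_p & ok_r))
    warning("class(es) with undefined precision/recall excluded from the weighted average")
  wavg <- function(v, use) sum(v[use] * wt[use]) / sum(wt[use])
  list(CA = sum(tp) / N,
       precision = wavg(prec, ok_p),
       recall = wavg(rec, ok_r),
       F1 = wavg(f1, ok_p & ok_r),
       per_class = data.frame(class = rownames(cm) %||% seq_len(nrow(cm)),
                              TP = tp, FP = fp, FN = fn, TN = tn,
                              precision = prec, recall = rec, F1 = f1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-vs-rest ROC curves and AUC
#'
#' For each class, the class's pooled probability scores against the
#' one-vs-rest label yield a ROC polygon (thresholds at distinct score
#' values, ties grouped) whose area is the trapezoid-rule AUC.  The
#' multiclass summary AUC is the class-size weighted average of the
#' one-vs-rest AUCs.
#'
#' @param probs n x K matrix of class probability scores, colnames =
#'   classes.
#' @param labels true classes, length n (must contain >= 2 classes).
#' @return list: `per_class` (each with `points` data.frame fpr/tpr and
#'   `auc`), `auc` (weighted average).
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least two classes")
  probs <- as.matrix(probs)
  per <- lapply(levels(labels), function(cl) {
    s <- probs[, cl]
    pos <- labels == cl
    np <- sum(pos); nn <- sum(!pos)
    ord <- order(-s)
    s_o <- s[ord]; p_o <- pos[ord]
    grp_last <- c(s_o[-1] != s_o[-length(s_o)], TRUE)  # last index of tie group
    tpr <- c(0, cumsum(p_o)[grp_last] / np)
    fpr <- c(0, cumsum(!p_o)[grp_last] / nn)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
  })
  names(per) <- levels(labels)
  wt <- as.numeric(table(labels))
  list(per_class = per,
       auc = sum(vapply(per, `[[`, numeric(1), "auc") * wt) / sum(wt))
}

#' Cross-validated evaluation of the five classifiers
#'
#' Stratified k-fold cross-validation of every model in `models` over the
#' PCA-projected features.  The standardize+PCA transform is refit inside
#' each training fold and applied to that fold's test split (no
#' information leakage from test cells into the projection;
#' `leaky_pca = TRUE` mimics workflows that fit PCA once on all data
#' before splitting).  Predictions are pooled over folds into one
#' confusion matrix and one probability table per model; the score table
#' is sorted by CA then precision, descending.  Deterministic given
#' `seed`.
#'
#' @param x `FeatureTable` or numeric feature matrix.
#' @param labels true class per row (taken from `x$class` when omitted and
#'   `x` is a table).
#' @param models list from [model_specs()].
#' @param folds number of folds (default 10); every class needs >= `folds`
#'   members.
#' @param seed integer seed controlling fold assignment and model fitting.
#' @param variance_target PCA explained-variance target (default 0.99).
#' @param feature_set `"all"`, `"rgb"` or `"gray"`.
#' @param leaky_pca fit PCA once on the full table instead of per fold.
#' @return object of class `"eval_report"`: `scores` (sorted data.frame:
#'   model, AUC, CA, F1, precision, recall), `best_model`, `confusion`
#'   (pooled confusion matrix of the best model), `roc` (its per-class ROC),
#'   `probs`/`predicted`/`labels` for the best model,
#'   `pca_components_used` (per-fold counts), `folds`, `seed`.
#' @examples
#' x <- matrix(rnorm(60 * 4), 60)
#' x[1:30, 1] <- x[1:30, 1] + 10
#' y <- rep(c("a", "b"), each = 30)
#' rep <- cross_validate(x, y, models = model_specs("knn"), folds = 5,
#'                       seed = 1)
#' rep$scores
#' @export
cross_validate <- function(x, labels = NULL, models = model_specs(),
                           folds = 10L, seed = 1L, variance_target = 0.99,
                           feature_set = "all", leaky_pca = FALSE) {
  if (is.null(labels)) {
    if (!is.data.frame(x) || !"class" %in% names(x))
      stop("labels missing and x has no class column")
    labels <- x$class
  }
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("need at least two classes to cross-validate")
  m <- .feature_matrix(x, feature_set)
  if (nrow(m) != length(y)) stop("feature rows and labels differ in length")
  fold_of <- with_seed(seed, function() .stratified_folds(y, folds))
  global_pca <- if (leaky_pca) select_pcs(m, variance_target) else NULL

  n <- nrow(m); K <- nlevels(y)
  probs <- lapply(models, function(.) matrix(NA_real_, n, K,
                                             dimnames = list(NULL, levels(y))))
  ks <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    if (leaky_pca) {
      pca <- global_pca
      str_tr <- predict(pca, m[tr, , drop = FALSE])
      str_te <- predict(pca, m[te, , drop = FALSE])
    } else {
      pca <- select_pcs(m[tr, , drop = FALSE], variance_target)
      str_tr <- pca$scores
      str_te <- predict(pca, m[te, , drop = FALSE])
    }
    ks[f] <- pca$k
    for (i in seq_along(models)) {
      fit <- fit_model(models[[i]], str_tr, y[tr],
                       seed = child_seed(seed, f * 100 + i))
      probs[[i]][te, ] <- predict_model(fit, str_te)
    }
  }

  rows <- vector("list", length(models))
  cms <- rocs <- preds <- vector("list", length(models))
  for (i in seq_along(models)) {
    pred <- factor(levels(y)[max.col(probs[[i]], ties.method = "first")],
                   levels = levels(y))
    cm <- table(true = y, predicted = pred)
    sc <- score_confusion(unclass(cm))
    roc <- roc_auc(probs[[i]], y)
    cms[[i]] <- cm; rocs[[i]] <- roc; preds[[i]] <- pred
    rows[[i]] <- data.frame(model = models[[i]]$label, AUC = roc$auc,
                            CA = sc$CA, F1 = sc$F1,
                            precision = sc$precision, recall = sc$recall,
                            stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  ord <- order(-scores$CA, -scores$precision)
  scores <- scores[ord, ]
  rownames(scores) <- NULL
  best <- ord[1]
  structure(list(scores = scores,
                 best_model = models[[best]]$label,
                 confusion = cms[[best]],
                 roc = rocs[[best]],
                 probs = probs[[best]],
                 predicted = preds[[best]],
                 labels = y,
                 pca_components_used = ks,
                 folds = folds, seed = seed,
                 feature_set = feature_set,
                 leaky_pca = leaky_pca),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (%d-fold, stratified, seed %s)\n",
              x$folds, format(x$seed)))
  cat(sprintf("PCA components per fold: %s\n",
              paste(x$pca_components_used, collapse = " ")))
  df <- x$scores
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  cat(sprintf("\nBest model: %s\nConfusion matrix (rows = true):\n",
              x$best_model))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object)
  invisible(object$scores)
}

#' Build an in-silico co-culture validation split
#'
#' Emulates validating mono-culture-trained classifiers on a virtual
#' mixture: from each class's feature table, `n_per_class` whole cells
#' (rows, keeping within-cell feature correlations) are drawn without
#' replacement and shuffled into one mixed validation set; all remaining
#' cells form the training set.  `marginal_resample = TRUE` implements the
#' alternative reading in which each feature column is resampled
#' independently within class, breaking within-cell correlations.
#'
#' @param tables named list (>= 2) of `FeatureTable`s, one per class; the
#'   list names become class labels.
#' @param n_per_class validation cells drawn per class (default: half of
#'   the smallest class).
#' @param seed integer seed.
#' @param marginal_resample resample feature values marginally instead of
#'   drawing whole rows.
#' @return list: `train`, `validation` (both `FeatureTable`s with `class`
#'   filled in).
#' @export
insilico_coculture <- function(tables, n_per_class = NULL, seed = 1L,
                               marginal_resample = FALSE) {
  if (length(tables) < 2) stop("need at least two classes")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (names = class labels)")
  sizes <- vapply(tables, nrow, integer(1))
  if (is.null(n_per_class)) n_per_class <- floor(min(sizes) / 2)
  if (any(n_per_class > sizes))
    stop("requested validation size exceeds a class table")
  with_seed(seed, function() {
    tr <- va <- list()
    for (cl in names(tables)) {
      tab <- tables[[cl]]
      tab$class <- cl
      pick <- sample.int(nrow(tab), n_per_class)
      if (marginal_resample) {
        v <- tab[pick, , drop = FALSE]
        for (col in feature_columns())
          v[[col]] <- sample(tab[[col]], n_per_class, replace = TRUE)
        va[[cl]] <- v
      } else va[[cl]] <- tab[pick, , drop = FALSE]
      tr[[cl]] <- tab[-pick, , drop = FALSE]
    }
    train <- do.call(rbind, tr)
    validation <- do.call(rbind, va)
    validation <- validation[sample.int(nrow(validation)), , drop = FALSE]
    rownames(train) <- rownames(validation) <- NULL
    list(train = train, validation = validation)
  })
}

#' Train on mono-cultures, score on an in-silico co-culture
#'
#' Fits the PCA transform and each model on the training split from
#' [insilico_coculture()] and scores the mixed validation split.
#'
#' @inheritParams insilico_coculture
#' @param models list from [model_specs()].
#' @param variance_target PCA explained-variance target.
#' @param feature_set feature subset.
#' @return `eval_report`-like object of class `"coculture_report"` with the
#'   same score-table layout.
#' @export
coculture_validate <- function(tables, models = model_specs(),
                               n_per_class = NULL, seed = 1L,
                               variance_target = 0.99, feature_set = "all",
                               marginal_resample = FALSE) {
  split <- insilico_coculture(tables, n_per_class, seed, marginal_resample)
  ytr <- factor(split$train$class)
  yva <- factor(split$validation$class, levels = levels(ytr))
  pca <- select_pcs(split$train, variance_target, feature_set)
  xtr <- pca$scores
  xva <- predict(pca, .feature_matrix(split$validation, feature_set))
  rows <- cms <- list()
  probs_best <- NULL
  for (i in seq_along(models)) {
    fit <- fit_model(models[[i]], xtr, ytr, seed = child_seed(seed, i))
    pr <- predict_model(fit, xva)
    pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                   levels = levels(ytr))
    cm <- table(true = yva, predicted = pred)
    sc <- score_confusion(unclass(cm))
    roc <- roc_auc(pr, yva)
    cms[[i]] <- cm
    rows[[i]] <- data.frame(model = models[[i]]$label, AUC = roc$auc,
                            CA = sc$CA, F1 = sc$F1,
                            precision = sc$precision, recall = sc$recall)
  }
  scores <- do.call(rbind, rows)
  ord <- order(-scores$CA, -scores$precision)
  scores <- scores[ord, ]; rownames(scores) <- NULL
  structure(list(scores = scores, best_model = scores$model[1],
                 confusion = cms[[ord[1]]],
                 pca_components_used = pca$k, seed = seed,
                 n_validation = nrow(split$validation)),
            class = c("coculture_report"))
}

#' @export
print.coculture_report <- function(x, ...) {
  cat(sprintf("In-silico co-culture validation (%d cells, seed %s)\n",
              x$n_validation, format(x$seed)))
  df <- x$scores; df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
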