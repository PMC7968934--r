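#' The five fixed-hyperparameter classifier specifications
#'
#' The model roster and every hyperparameter are fixed (no tuning):
#' \itemize{
#'   \item kNN: 5 neighbours, Euclidean metric, uniform weights.
#'   \item Logistic regression: L1 (lasso) penalty, strength C = 1.
#'   \item Random forest: 10 trees, depth limited to 5, nodes smaller than
#'     5 not split.
#'   \item SVM: linear kernel, cost C = 1, numerical tolerance 0.001,
#'     iteration limit 100 (the libsvm backend does not expose an iteration
#'     cap, so the limit is recorded but cannot be enforced; the
#'     regression epsilon 0.1 is meaningless for classification and is
#'     recorded unused).
#'   \item Neural network: one hidden layer of 200 ReLU units, softmax
#'     output, Adam solver, L2 regularization alpha = 1e-4, 200 epochs.
#' }
#'
#' @param which subset of model names to return.
#' @return named list of `model_spec` objects.
#' @export
model_specs <- function(which = c("knn", "logistic", "random_forest",
                                  "svm", "neural_net")) {
  all <- list(
    knn = list(name = "knn", label = "kNN",
               params = list(n_neighbors = 5L, metric = "euclidean",
                             weights = "uniform")),
    logistic = list(name = "logistic", label = "Logistic Regression",
                    params = list(penalty = "l1", C = 1)),
    random_forest = list(name = "random_forest", label = "Random Forest",
                         params = list(n_trees = 10L, max_depth = 5L,
                                       min_split = 5L)),
    svm = list(name = "svm", label = "SVM",
               params = list(kernel = "linear", C = 1, epsilon = 0.1,
                             tol = 0.001, max_iter = 100L)),
    neural_net = list(name = "neural_net", label = "Neural Network",
                      params = list(hidden = 200L, activation = "relu",
                                    solver = "adam", alpha = 1e-4,
                                    max_iter = 200L)))
  which <- match.arg(which, several.ok = TRUE)
  lapply(all[which], function(m) structure(m, class = "model_spec"))
}

# ---- unified learner interface -------------------------------------------
# fit_model(spec, x, y, seed) -> fitted object
# predict_model(fit, x)       -> n x K probability matrix, colnames = levels

fit_model <- function(spec, x, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  fitter <- switch(spec$name,
                   knn = .fit_knn, logistic = .fit_logistic,
                   random_forest = .fit_rf, svm = .fit_svm,
                   neural_net = .fit_mlp,
                   stop("unknown model: ", spec$name))
  fit <- with_seed(seed, function() fitter(spec, x, y))
  structure(list(spec = spec, fit = fit, levels = levels(y)),
            class = "chromocell_fit")
}

predict_model <- function(object, x) {
  pr <- switch(object$spec$name,
               knn = .predict_knn(object$fit, x),
               logistic = .predict_logistic(object$fit, x),
               random_forest = .predict_rf(object$fit, x),
               svm = .predict_svm(object$fit, x),
               neural_net = .predict_mlp(object$fit, x))
  pr <- pr[, object$levels, drop = FALSE]
  pr / pmax(rowSums(pr), .Machine$double.eps)
}

# ---- kNN: Euclidean vote fractions ---------------------------------------
# Direct implementation so per-class vote fractions (needed for ROC) are
# available; ties in distance break by training-row order.

.fit_knn <- function(spec, x, y)
  list(x = as.matrix(x), y = y, k = spec$params$n_neighbors)

.predict_knn <- function(fit, x) {
  x <- as.matrix(x)
  k <- min(fit$k, nrow(fit$x))
  d2 <- outer(rowSums(x^2), rep(1, nrow(fit$x))) +
    outer(rep(1, nrow(x)), rowSums(fit$x^2)) - 2 * x %*% t(fit$x)
  lev <- levels(fit$y)
  pr <- t(apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    tabulate(as.integer(fit$y[nn]), length(lev)) / k
  }))
  colnames(pr) <- lev
  pr
}

# ---- L1 logistic regression via glmnet -----------------------------------
# The C-parameterized objective C*sum(loss) + ||w||_1 maps onto glmnet's
# (1/n)*sum(loss) + lambda*||w||_1 at lambda = 1/(n*C).  Inputs are PCA
# scores of standardized features, so no further standardization.

.fit_logistic <- function(spec, x, y) {
  x <- as.matrix(x)
  lambda <- 1 / (nrow(x) * spec$params$C)
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  glmnet::glmnet(x, y, family = fam, alpha = 1,
                 lambda = c(lambda * 10, lambda),  # short path aids convergence
                 standardize = FALSE, thresh = 1e-9)
}

.predict_logistic <- function(fit, x) {
  x <- as.matrix(x)
  lam <- min(fit$lambda)
  p <- predict(fit, newx = x, s = lam, type = "response")
  if (length(dim(p)) == 3L) {
    pr <- p[, , 1, drop = TRUE]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                       dimnames = list(NULL, dimnames(p)[[2]]))
  } else {
    cls <- fit$classnames
    pr <- cbind(1 - p[, 1], p[, 1])
    colnames(pr) <- cls
  }
  pr
}

# ---- random forest via ranger --------------------------------------------

.fit_rf <- function(spec, x, y) {
  df <- as.data.frame(x)
  ranger::ranger(y = y, x = df,
                 num.trees = spec$params$n_trees,
                 max.depth = spec$params$max_depth,
                 min.node.size = spec$params$min_split,
                 probability = TRUE, num.threads = 1L,
                 seed = sample.int(.Machine$integer.max, 1L))
}

.predict_rf <- function(fit, x)
  predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions

# ---- linear SVM via e1071 (libsvm) ---------------------------------------
# Probability scores are derived from decision values (pairwise values
# summed per class, then min-max scaled over the scored set), since the
# printed configuration does not include probability calibration.

.fit_svm <- function(spec, x, y)
  e1071::svm(as.matrix(x), y, kernel = "linear", cost = spec$params$C,
             tolerance = spec$params$tol, scale = FALSE)

.predict_svm <- function(fit, x) {
  pred <- predict(fit, as.matrix(x), decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lev <- fit$levels
  score <- matrix(0, nrow(dv), length(lev), dimnames = list(NULL, lev))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    score[, pair[1]] <- score[, pair[1]] + dv[, cn]
    score[, pair[2]] <- score[, pair[2]] - dv[, cn]
  }
  rng <- range(score)
  if (diff(rng) > 0) score <- (score - rng[1]) / diff(rng)
  else score[] <- 1 / length(lev)
  score
}

# ---- neural network: 1 hidden layer, ReLU, softmax, Adam -----------------
# Authored here so the stated architecture and optimizer are honored
# exactly: hidden = 200 ReLU units, cross-entropy + (alpha/2)*||W||^2,
# Adam (lr 1e-3, beta1 .9, beta2 .999, eps 1e-8), minibatches of
# min(200, n), max_iter epochs.

.fit_mlp <- function(spec, x, y) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x); H <- spec$params$hidden
  K <- nlevels(y)
  yi <- as.integer(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1
  glorot <- function(fan_in, fan_out)
    matrix(runif(fan_in * fan_out, -1, 1) * sqrt(6 / (fan_in + fan_out)),
           fan_in, fan_out)
  W1 <- glorot(p, H); b1 <- rep(0, H)
  W2 <- glorot(H, K); b2 <- rep(0, K)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- v <- lapply(params, function(z) z * 0)
  alpha <- spec$params$alpha
  lr <- 1e-3; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  batch <- min(200L, n)
  t_step <- 0
  for (epoch in seq_len(spec$params$max_iter)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      nb <- length(idx)
      Xb <- x[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      A1 <- sweep(Xb %*% params$W1, 2L, params$b1, "+")
      Z1 <- pmax(A1, 0)
      A2 <- sweep(Z1 %*% params$W2, 2L, params$b2, "+")
      A2 <- A2 - apply(A2, 1L, max)
      P <- exp(A2); P <- P / rowSums(P)
      dA2 <- (P - Yb) / nb
      g <- list(
        W1 = NULL, b1 = NULL,
        W2 = t(Z1) %*% dA2 + alpha * params$W2 / n,
        b2 = colSums(dA2))
      dZ1 <- (dA2 %*% t(params$W2)) * (A1 > 0)
      g$W1 <- t(Xb) %*% dZ1 + alpha * params$W1 / n
      g$b1 <- colSums(dZ1)
      t_step <- t_step + 1
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t_step)
        vhat <- v[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  c(params, list(levels = levels(y)))
}

.predict_mlp <- function(fit, x) {
  x <- as.matrix(x)
  Z1 <- pmax(sweep(x %*% fit$W1, 2L, fit$b1, "+"), 0)
  A2 <- sweep(Z1 %*% fit$W2, 2L, fit$b2, "+")
  A2 <- A2 - apply(A2, 1L, max)
  P <- exp(A2); P <- P / rowSums(P)
  colnames(P) <- fit$levels
  P
}
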