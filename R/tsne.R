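#' t-SNE embedding of a per-cell feature table
#'
#' Exact (dense) t-distributed stochastic neighbour embedding for visual
#' inspection of class separation: Gaussian input affinities calibrated per
#' point to the target perplexity by bisection, symmetrized and normalized;
#' Student-t (1 df) low-dimensional kernel; gradient descent with momentum
#' (0.5 rising to 0.8 after 250 steps) and early exaggeration (x12 for the
#' first 100 steps).  Quadratic in the number of cells, which is fine at
#' the few-hundred-cell scale of per-line feature tables.  The input is
#' expected to be PCA scores (see [select_pcs()]); the embedding is
#' centered at the origin and deterministic given `seed`.
#'
#' @param x numeric matrix of PCA scores (or a `FeatureTable`, projected
#'   with [select_pcs()] first).
#' @param perplexity target perplexity (default 30); must satisfy
#'   `perplexity < (n - 1) / 3`.
#' @param variance_target PCA target used when `x` is a raw table.
#' @param n_iter gradient-descent steps.
#' @param seed integer seed for the initial layout.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, variance_target = 0.99,
                       n_iter = 500L, seed = 1L) {
  if (is.data.frame(x)) x <- select_pcs(x, variance_target)$scores
  x <- as.matrix(x)
  n <- nrow(x)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large: need perplexity < (n_samples - 1) / 3")
  d2 <- as.matrix(stats::dist(x))^2
  P <- .tsne_affinities(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)
  with_seed(seed, function() {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    eta <- 200
    for (iter in seq_len(n_iter)) {
      exag <- if (iter <= 100) 12 else 1
      mom <- if (iter <= 250) 0.5 else 0.8
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- num / sum(num)
      Q <- pmax(Q, .Machine$double.xmin)
      L <- (exag * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
  })
}

# per-point bisection on the Gaussian precision so each row of the
# conditional affinity matrix has entropy log(perplexity)
.tsne_affinities <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}
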