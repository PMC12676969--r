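#' Two-dimensional t-SNE embedding with per-cluster confidence ellipses
#'
#' Exact (dense) t-distributed stochastic neighbour embedding of the sample
#' profiles, suitable for the cohort sizes this pipeline targets (tens to a
#' few hundred samples). Perplexity is calibrated per sample by binary
#' search; the low-dimensional layout is optimised by gradient descent with
#' momentum and early exaggeration. Deterministic given `seed`.
#'
#' If cluster assignments are supplied, a 95% bivariate-normal contour is
#' computed for each cluster from the embedded coordinates.
#'
#' @param X numeric matrix, samples in rows.
#' @param seed RNG seed for the initial layout.
#' @param perplexity t-SNE perplexity; default `min(30, floor((n-1)/3))`.
#' @param clusters optional per-sample labels for the ellipses.
#' @param max_iter gradient-descent iterations.
#' @return a list with `coords` (n x 2 matrix), `perplexity`, and `ellipses`
#'   (per cluster: centre, covariance and a 100-point 95% contour polygon).
#' @export
embed_2d <- function(X, seed = 1, perplexity = NULL, clusters = NULL,
                     max_iter = 400) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("at least 4 samples are required for embedding")
  if (is.null(perplexity)) perplexity <- min(30, floor((n - 1) / 3))
  if (perplexity >= (n - 1) / 3 + 1e-9 && perplexity > floor((n - 1) / 3))
    stop("perplexity too large for the number of samples")
  P <- tsne_affinities(X, perplexity)
  Y <- withr::with_seed(seed_stream(seed, "tsne"),
                        matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  Y <- tsne_optimise(P, Y, max_iter = max_iter)
  rownames(Y) <- rownames(X)
  ellipses <- NULL
  if (!is.null(clusters)) {
    ellipses <- lapply(split(seq_len(n), clusters), function(idx) {
      if (length(idx) < 3) return(NULL)
      ctr <- colMeans(Y[idx, , drop = FALSE])
      S <- stats::cov(Y[idx, , drop = FALSE])
      confidence_ellipse(ctr, S, level = 0.95)
    })
  }
  list(coords = Y, perplexity = perplexity, ellipses = ellipses)
}

# symmetrised input affinities with per-point entropy calibration
tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

tsne_optimise <- function(P, Y, max_iter = 400, exaggeration = NULL,
                          stop_lying = 100, eta = NULL) {
  n <- nrow(Y)
  # scale optimiser constants down for small cohorts to keep the gradient
  # descent stable
  if (is.null(exaggeration)) exaggeration <- min(12, max(1, n / 8))
  if (is.null(eta)) eta <- max(10, min(200, n))
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  Pe <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Puse <- if (iter <= stop_lying) Pe else P
    D2 <- as.matrix(dist(Y))^2
    W <- 1 / (1 + D2)
    diag(W) <- 0
    Q <- pmax(W / sum(W), .Machine$double.xmin)
    L <- (Puse - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

confidence_ellipse <- function(center, S, level = 0.95, n_points = 100) {
  r <- sqrt(qchisq(level, df = 2))
  eig <- eigen(S, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circle <- rbind(cos(theta), sin(theta)) * r
  pts <- t(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * circle) + center)
  colnames(pts) <- c("x", "y")
  list(center = center, cov = S, polygon = pts)
}
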