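# Exact-gradient t-SNE.  No t-SNE implementation ships with the installed
# R stack, so the standard algorithm is implemented here: per-point
# precision calibration to a target perplexity by bisection, PCA
# pre-reduction and PCA-based initialisation, early exaggeration, momentum
# gradient descent on the Kullback-Leibler divergence between input
# affinities and Student-t low-dimensional affinities.

# Row-wise conditional affinities at a target perplexity via bisection on
# the Gaussian precision.
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 60) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 10; next }
      p <- w / sw
      ent <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(ent - target) < tol) break
      if (ent > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2D embedding of a feature table by t-SNE
#'
#' Maps gene-pair feature rows to 2D by t-distributed stochastic neighbor
#' embedding, after an initial PCA reduction.  The embedding is
#' initialised from the first two (scaled) principal components plus a
#' small seeded jitter, so duplicated rows start together and the
#' cluster-level structure is stable across seeds.
#'
#' @param X numeric feature matrix or `feature_table` (rows = gene pairs).
#' @param perplexity effective neighborhood size; capped with a warning at
#'   `(n - 1) / 3` for small inputs.
#' @param init_dims number of principal components kept before t-SNE,
#'   capped at `min(ncol, n - 1)`.
#' @param seed seed for the initialisation jitter.
#' @param max_iter gradient-descent iterations.
#' @return n x 2 matrix of coordinates.
#' @export
embed_2d <- function(X, perplexity = 30, init_dims = 50, seed = 1,
                     max_iter = 500) {
  if (inherits(X, "feature_table")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 rows to embed", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0) stop("all features constant", call. = FALSE)
  }
  if (perplexity > (n - 1) / 3) {
    perplexity <- max(2, (n - 1) / 3)
    warning("perplexity too large for n; capped at ", signif(perplexity, 3))
  }
  k <- min(init_dims, ncol(X), n - 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  Zall <- pc$x[, seq_len(k), drop = FALSE]
  # collapse exact duplicates: identical feature profiles get identical
  # coordinates by construction, and the gradient flow never has to keep
  # coincident points together
  key <- apply(Zall, 1, paste, collapse = "\r")
  uid <- match(key, unique(key))
  Z <- Zall[!duplicated(uid), , drop = FALSE]
  nu <- nrow(Z)
  if (nu < 4) stop("need at least 4 distinct rows to embed", call. = FALSE)
  if (perplexity > (nu - 1) / 3) {
    perplexity <- max(2, (nu - 1) / 3)
  }
  D2 <- as.matrix(stats::dist(Z))^2
  P <- tsne_affinities(D2, perplexity)

  # PCA initialisation, scaled small, with seeded jitter
  Y <- Z[, 1:2, drop = FALSE]
  if (ncol(Y) < 2) Y <- cbind(Y, 0)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Y <- Y / max(stats::sd(Y[, 1]), 1e-12) * 1e-4
  Y <- Y + with_seed(seed, matrix(stats::rnorm(nu * 2, sd = 1e-6), nu, 2))

  vel <- matrix(0, nu, 2)
  gains <- matrix(1, nu, 2)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1
    mom <- if (iter <= 250) 0.5 else 0.8
    D2y <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + D2y)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    M <- (ex * P - Q) * num
    grad <- 4 * (rowSums(M) * Y - M %*% Y)
    gains <- pmax(0.01, ifelse(sign(grad) != sign(vel),
                               gains + 0.2, gains * 0.8))
    vel <- mom * vel - 200 * gains * grad
    Y <- Y + vel
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  Y <- Y[uid, , drop = FALSE]
  dimnames(Y) <- list(rownames(X), c("tsne1", "tsne2"))
  Y
}
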