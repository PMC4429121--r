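#' Diffusion-scale schedule
#'
#' The geometric schedule of diffusion scales used for the scale-aware
#' topological measures: `b` steps uniformly from 0 to 1 and
#' `beta = (2^(6 b) - 1) / (2^6 - 1) * (beta_max - beta_min) + beta_min`,
#' concentrating scales near 0 where the kernel changes fastest.  The
#' default 10-point schedule is
#' `0.0001, 0.09, 0.24, 0.47, 0.8, 1.4, 2.3, 3.8, 6.2, 10` (to the
#' precision shown).
#'
#' @param n_steps number of scales (>= 2).
#' @param beta_min,beta_max schedule endpoints.
#' @return numeric vector of length `n_steps`.
#' @export
beta_schedule <- function(n_steps = 10, beta_min = 1e-4, beta_max = 10) {
  if (n_steps < 2) stop("n_steps must be >= 2", call. = FALSE)
  b <- seq(0, 1, length.out = n_steps)
  (2^(6 * b) - 1) / (2^6 - 1) * (beta_max - beta_min) + beta_min
}

# Eigendecomposition of the graph operator A - D (negative Laplacian),
# reused across scales when many kernels of one network are needed.
laplacian_eigen <- function(cin) {
  A <- cin$A
  lap <- A
  diag(lap) <- diag(lap) - rowSums(A)
  eigen(lap, symmetric = TRUE)
}

kernel_from_eigen <- function(eig, beta) {
  K <- eig$vectors %*% (exp(beta * eig$values) * t(eig$vectors))
  K <- (K + t(K)) / 2   # kill round-off asymmetry
  K[K < 0] <- 0
  K
}

#' Diffusion kernel of a network
#'
#' The matrix exponential `K^beta = exp(beta (A - D))` computed by
#' symmetric eigendecomposition of `A - D` (adjacency minus degree matrix).
#' `K^beta` is symmetric, non-negative, doubly stochastic; `beta` sets the
#' topological scale, from the identity at `beta = 0` to uniformity over
#' each connected component as `beta` grows.
#'
#' @param cin a `cin` (see [build_cin()]).
#' @param beta diffusion scale, >= 0.
#' @return an object of class `diffusion_kernel` with fields `beta` and the
#'   kernel matrix `K`.
#' @export
diffusion_kernel <- function(cin, beta) {
  stopifnot(inherits(cin, "cin"))
  stopifnot_scalar(beta, "beta")
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  K <- kernel_from_eigen(laplacian_eigen(cin), beta)
  dimnames(K) <- dimnames(cin$A)
  structure(list(beta = beta, K = K), class = "diffusion_kernel")
}

#' @export
print.diffusion_kernel <- function(x, ...) {
  cat(sprintf("<diffusion_kernel> %d nodes, beta = %g\n", nrow(x$K), x$beta))
  invisible(x)
}

#' Standard topological measures of a CIN
#'
#' Node measures: degree `deg(x)`; closeness `c(x) = 1 / sum_i s(x, i)`
#' (0 for isolated nodes); shortest-path betweenness `b(x)` with
#' all-geodesic counting, endpoints excluded; local clustering coefficient
#' `cc(x)` over the open neighborhood.  Link measures: unweighted
#' shortest-path length `s(x, y)` in edges, and the Jaccard index
#' `J(x, y)` of open neighborhoods.  Unreachable pairs take the finite cap
#' `s = N` (the node count), also used inside closeness sums.
#'
#' @param cin a `cin`.
#' @param centrality which node-centrality fills the 8-feature centrality
#'   slot downstream: `"closeness"` (default; its scale-aware analogue is
#'   closeness-like) or `"degree"`.
#' @return list with `node` (data.frame: `degree`, `closeness`,
#'   `betweenness`, `clustering`, plus `centrality` = the chosen slot) and
#'   matrices `s` and `J`.
#' @export
standard_measures <- function(cin, centrality = c("closeness", "degree")) {
  centrality <- match.arg(centrality)
  stopifnot(inherits(cin, "cin"))
  A <- cin$A
  N <- nrow(A)
  g <- cin_graph(cin)
  s <- igraph::distances(g)
  s[is.infinite(s)] <- N
  deg <- rowSums(A)
  clo <- vapply(seq_len(N), function(x) {
    if (deg[x] == 0 || N == 1) 0 else 1 / sum(s[x, -x])
  }, numeric(1))
  btw <- igraph::betweenness(g, directed = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  common <- A %*% A
  uni <- outer(deg, deg, "+") - common
  J <- ifelse(uni > 0, common / uni, 0)
  node <- data.frame(degree = deg, closeness = clo,
                     betweenness = as.numeric(btw), clustering = cc)
  node$centrality <- node[[centrality]]
  list(node = node, s = s, J = J)
}

#' Scale-aware topological measures from a diffusion kernel
#'
#' The diffusion analogues of the standard measures, all evaluated on
#' `K = K^beta` with sums running over every node:
#' `s(x,y) = -log K(x,y)` (zero kernel entries capped at `eps`);
#' `J(x,y) = sum_i min(K(x,i), K(i,y)) / sum_i max(K(x,i), K(i,y))`;
#' closeness-like centrality `c(x) = 1 - K(x,x)`;
#' `b(z) = 1/N^2 sum_{x,y} (s(x,y) - s(x,z) - s(z,y))` (may be negative);
#' `cc(x) = sum_{i != x} K(x,i) J(x,i)`.
#'
#' @param k a `diffusion_kernel`.
#' @param eps floor applied to kernel entries before the log, so pairs in
#'   distinct components get the finite cap `-log(eps)`.
#' @return list with `node` (data.frame: `centrality`, `betweenness`,
#'   `clustering`) and matrices `s` and `J`.
#' @export
scale_aware_measures <- function(k, eps = 1e-12) {
  stopifnot(inherits(k, "diffusion_kernel"))
  K <- k$K
  N <- nrow(K)
  s <- -log(pmax(K, eps))
  rs <- rowSums(K)
  # sum_i min(a_i, b_i) = (sum a + sum b - sum |a_i - b_i|)/2, and the L1
  # distances between kernel rows come from a single dist() call
  l1 <- as.matrix(stats::dist(K, method = "manhattan"))
  tot <- outer(rs, rs, "+")
  J <- (tot - l1) / (tot + l1)
  cen <- 1 - diag(K)
  btw <- sum(s) / N^2 - 2 * rowSums(s) / N
  cc <- rowSums(K * J) - diag(K) * diag(J)
  list(node = data.frame(centrality = cen, betweenness = btw, clustering = cc),
       s = s, J = J)
}

#' Link features of gene pairs from one measure set
#'
#' Converts node measures to link measures by taking the absolute
#' difference and the average per pair, and appends the two intrinsically
#' link-based measures, giving exactly 8 features per pair:
#' `s`, `J`, `|dc|`, `mc`, `|db|`, `mb`, `|dcc|`, `mcc` (centrality,
#' betweenness, clustering).  Defined for every requested pair, not only
#' network links.
#'
#' @param meas output of [standard_measures()] or [scale_aware_measures()].
#' @param pairs 2-column matrix of node indices (or character node names
#'   resolved against `nodes`).
#' @param nodes node-name vector of the CIN the measures came from
#'   (required when `pairs` is character).
#' @param tag feature-name tag `"<scale|std>|<resolution>|<mapping>"`
#'   appended to each measure name.
#' @return numeric matrix, one row per pair, 8 named columns.
#' @export
link_features <- function(meas, pairs, nodes = NULL, tag = "") {
  if (is.character(pairs)) {
    if (is.null(nodes)) stop("'nodes' needed to resolve pair names", call. = FALSE)
    idx <- cbind(match(pairs[, 1], nodes), match(pairs[, 2], nodes))
    if (anyNA(idx)) stop("pair references node absent from CIN", call. = FALSE)
  } else {
    idx <- as.matrix(pairs)
  }
  i <- idx[, 1]; j <- idx[, 2]
  nd <- meas$node
  out <- cbind(
    s         = meas$s[idx],
    J         = meas$J[idx],
    c_absdiff = abs(nd$centrality[i] - nd$centrality[j]),
    c_mean    = (nd$centrality[i] + nd$centrality[j]) / 2,
    b_absdiff = abs(nd$betweenness[i] - nd$betweenness[j]),
    b_mean    = (nd$betweenness[i] + nd$betweenness[j]) / 2,
    cc_absdiff = abs(nd$clustering[i] - nd$clustering[j]),
    cc_mean   = (nd$clustering[i] + nd$clustering[j]) / 2
  )
  if (nzchar(tag)) colnames(out) <- paste(colnames(out), tag, sep = "|")
  out
}

#' Assemble the gene-pair feature table over networks and scales
#'
#' Column-wise concatenation of 8-feature blocks: one block per CIN for the
#' standard measures and one per (CIN, beta) for the scale-aware measures.
#' With the default 10-scale schedule, a single CIN yields 80 scale-aware
#' columns, and the full grid of 5 resolutions x 2 mappings yields 800.
#' Column names follow `"<measure>|<scale|std>|<resolution>|<mapping>"`.
#'
#' @param cins list of `cin` objects over one shared gene universe.
#' @param pairs 2-column character matrix (or data.frame) of gene-id pairs;
#'   every gene must be a node of every CIN.
#' @param mode `"stm"`, `"standard"`, or `"both"`.
#' @param betas diffusion scales for the scale-aware blocks.
#' @param centrality centrality slot for the standard blocks (see
#'   [standard_measures()]).
#' @return list of class `feature_table`: `pairs` (data.frame `geneA`,
#'   `geneB`) and numeric feature matrix `X`.
#' @export
assemble_features <- function(cins, pairs, mode = c("stm", "standard", "both"),
                              betas = beta_schedule(),
                              centrality = "closeness") {
  mode <- match.arg(mode)
  if (inherits(cins, "cin")) cins <- list(cins)
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  blocks <- list()
  for (cin in cins) {
    idx <- cbind(match(pairs[, 1], cin$nodes), match(pairs[, 2], cin$nodes))
    if (anyNA(idx)) stop("mismatched pair universes across CINs", call. = FALSE)
    base_tag <- paste(format(cin$resolution, scientific = FALSE), cin$mapping,
                      sep = "|")
    if (mode %in% c("standard", "both")) {
      ms <- standard_measures(cin, centrality = centrality)
      blocks[[length(blocks) + 1L]] <-
        link_features(ms, idx, tag = paste("std", base_tag, sep = "|"))
    }
    if (mode %in% c("stm", "both")) {
      eig <- laplacian_eigen(cin)
      for (beta in betas) {
        k <- structure(list(beta = beta,
                            K = kernel_from_eigen(eig, beta)),
                       class = "diffusion_kernel")
        blocks[[length(blocks) + 1L]] <-
          link_features(scale_aware_measures(k), idx,
                        tag = paste(signif(beta, 3), base_tag, sep = "|"))
      }
    }
  }
  X <- do.call(cbind, blocks)
  structure(
    list(pairs = data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                            stringsAsFactors = FALSE),
         X = X),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d pairs x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Write a feature table as TSV
#' @param ft a `feature_table`.
#' @param path output file; columns `geneA geneB <feature names>`.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.table(cbind(ft$pairs, as.data.frame(ft$X)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
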