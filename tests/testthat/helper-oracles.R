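# Independent oracles used to validate the implementation.  Everything in
# this file is deliberately brute force and shares no code with the package
# internals.

# --- graph oracles (exhaustive BFS / path enumeration) ----------------------

# All-pairs shortest-path lengths by breadth-first search from every node;
# unreachable pairs get the finite cap N.
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  out <- matrix(n, n, n)
  diag(out) <- 0
  for (s in seq_len(n)) {
    distv <- rep(NA_integer_, n)
    distv[s] <- 0L
    frontier <- s
    d <- 0L
    while (length(frontier) > 0) {
      d <- d + 1L
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] == 1)
        nb <- nb[is.na(distv[nb])]
        distv[nb] <- d
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    reach <- !is.na(distv)
    out[s, reach] <- distv[reach]
  }
  out
}

# Geodesic counts between every pair, by enumerating ALL simple paths
# (feasible only for tiny graphs).
oracle_path_enumeration <- function(A) {
  n <- nrow(A)
  sp <- oracle_shortest_paths(A)
  cnt <- matrix(0, n, n)           # number of geodesics between i and j
  through <- array(0, c(n, n, n))  # ... passing through z (interior)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(visited))
    out <- list()
    for (v in which(A[from, ] == 1)) {
      if (!v %in% visited) {
        out <- c(out, all_paths(v, to, c(visited, v)))
      }
    }
    out
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || sp[i, j] >= n) next
    paths <- all_paths(i, j, i)
    geo <- Filter(function(p) length(p) - 1 == sp[i, j], paths)
    cnt[i, j] <- length(geo)
    for (p in geo) {
      interior <- setdiff(p, c(i, j))
      for (z in interior) through[i, j, z] <- through[i, j, z] + 1
    }
  }
  list(sp = sp, cnt = cnt, through = through)
}

# Betweenness b(z) = sum over unordered pairs {i, j} (z not endpoint) of
# q_ij(z) / q_ij, all geodesics counted.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  pe <- oracle_path_enumeration(A)
  vapply(seq_len(n), function(z) {
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (i == z || j == z || pe$cnt[i, j] == 0) next
      tot <- tot + pe$through[i, j, z] / pe$cnt[i, j]
    }
    tot
  }, numeric(1))
}

# Local clustering over the open neighborhood.
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(x) {
    nb <- which(A[x, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

# Jaccard index of open neighborhoods.
oracle_jaccard <- function(A) {
  n <- nrow(A)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- which(A[i, ] == 1); nj <- which(A[j, ] == 1)
    u <- union(ni, nj)
    J[i, j] <- if (length(u) == 0) 0 else length(intersect(ni, nj)) / length(u)
  }
  J
}

# Closeness with the package's conventions: cap N for unreachable,
# 0 for isolated nodes.
oracle_closeness <- function(A) {
  n <- nrow(A)
  sp <- oracle_shortest_paths(A)
  vapply(seq_len(n), function(x) {
    if (sum(A[x, ]) == 0 || n == 1) 0 else 1 / sum(sp[x, -x])
  }, numeric(1))
}

# --- kernel oracle ----------------------------------------------------------

# Matrix exponential of beta (A - D) by truncated Taylor series.
oracle_kernel_taylor <- function(A, beta, terms = 50) {
  n <- nrow(A)
  M <- beta * (A - diag(rowSums(A)))
  K <- diag(n)
  term <- diag(n)
  for (t in seq_len(terms)) {
    term <- term %*% M / t
    K <- K + term
  }
  K
}

# --- rank-normalization oracle ----------------------------------------------

# Sort-based ranking of a value vector (average ranks on ties), computed by
# explicit order statistics rather than rank().
oracle_sort_ranks <- function(pool) {
  srt <- sort(pool)
  vapply(pool, function(v) {
    lo <- sum(srt < v)
    eq <- sum(srt == v)
    lo + (1 + eq) / 2
  }, numeric(1))
}

# --- misc -------------------------------------------------------------------

# Seeded Erdos-Renyi-style random adjacency matrix.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < p)
  A + t(A)
}

# Wrap an adjacency matrix as a minimal CIN-like object.
as_test_cin <- function(A, nodes = paste0("g", seq_len(nrow(A)))) {
  dimnames(A) <- list(nodes, nodes)
  structure(list(chrom = "chrT", resolution = 4e4, mapping = "MAX",
                 nodes = nodes, A = A),
            class = "cin")
}

# Small contact matrix with seeded random integer counts.
random_contact <- function(n, seed, lambda = 20, chrom = "chrT") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * n, lambda), n, n)
  })
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, chrom = chrom, bin_size = 4e4)
}
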