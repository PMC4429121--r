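test_that("beta schedule reproduces the documented 10-point grid", {
  s <- beta_schedule()
  expect_length(s, 10)
  expect_equal(s[1], 1e-4)
  expect_equal(s[10], 10)
  expect_true(all(diff(s) > 0))
  # values as printed (truncated to the shown digits)
  printed <- c(0.0001, 0.09, 0.24, 0.47, 0.8, 1.4, 2.3, 3.8, 6.2, 10)
  digits <- c(4, 2, 2, 2, 1, 1, 1, 1, 1, 0)
  trunc_to <- function(x, d) floor(x * 10^d) / 10^d
  expect_equal(trunc_to(s, digits), printed)
  # sixth value rounds to 1.4 at one decimal
  expect_equal(round(s[6], 1), 1.4)
  # direct evaluation of the formula at b = 5/9
  expect_equal(s[6], (2^(6 * 5 / 9) - 1) / 63 * (10 - 1e-4) + 1e-4)
})

test_that("diffusion kernel identities hold", {
  withr::with_seed(101, {
    A <- random_adjacency(9, 0.35)
  })
  cin <- as_test_cin(A)
  # beta = 0 gives the identity
  expect_equal(unname(diffusion_kernel(cin, 0)$K), diag(9), tolerance = 1e-12)
  # rows sum to one; symmetric; entries in [0, 1]
  for (beta in c(0.09, 0.8, 3.8)) {
    K <- diffusion_kernel(cin, beta)$K
    expect_equal(unname(rowSums(K)), rep(1, 9), tolerance = 1e-9)
    expect_equal(K, t(K))
    expect_true(all(K >= 0 & K <= 1 + 1e-12))
  }
})

test_that("two-node kernel matches the closed form from eigenvalues {0, -2}", {
  cin <- as_test_cin(rbind(c(0, 1), c(1, 0)))
  for (beta in c(0.1, 0.8, 2.3)) {
    K <- diffusion_kernel(cin, beta)$K
    expect_equal(unname(K),
                 rbind(c((1 + exp(-2 * beta)) / 2, (1 - exp(-2 * beta)) / 2),
                       c((1 - exp(-2 * beta)) / 2, (1 + exp(-2 * beta)) / 2)),
                 tolerance = 1e-12)
  }
})

test_that("large beta drives each row to uniformity over its component", {
  # two components: a 4-clique and a 3-path
  A <- matrix(0, 7, 7)
  A[1:4, 1:4] <- 1; diag(A) <- 0
  A[5, 6] <- A[6, 5] <- A[6, 7] <- A[7, 6] <- 1
  K <- diffusion_kernel(as_test_cin(A), 50)$K
  expect_lt(max(abs(K[1:4, 1:4] - 1 / 4)), 1e-6)
  expect_lt(max(abs(K[5:7, 5:7] - 1 / 3)), 1e-6)
  expect_lt(max(abs(K[1:4, 5:7])), 1e-6)
})

test_that("kernel diffusion strength grows with beta for connected pairs near zero", {
  withr::with_seed(103, A <- random_adjacency(8, 0.5))
  cin <- as_test_cin(A)
  K1 <- diffusion_kernel(cin, 0.01)$K
  K2 <- diffusion_kernel(cin, 0.05)$K
  linked <- A == 1
  expect_true(all(K2[linked] > K1[linked]))
})

test_that("kernel matches a 50-term Taylor-series oracle on 8-node graphs", {
  withr::with_seed(107, {
    for (rep in 1:10) {
      A <- random_adjacency(8, runif(1, 0.2, 0.7))
      # moderate scales: the truncated series itself loses accuracy once
      # ||beta (A - D)|| approaches the number of terms
      beta <- runif(1, 0.05, 1.5)
      K <- diffusion_kernel(as_test_cin(A), beta)$K
      expect_lt(max(abs(K - oracle_kernel_taylor(A, beta))), 1e-8)
    }
  })
})

test_that("standard measures match hand-enumerated small graphs", {
  # triangle: cc = 1, J = 1/3 on links, s = 1
  tri <- as_test_cin(matrix(1, 3, 3) - diag(3))
  mt <- standard_measures(tri)
  expect_equal(mt$node$clustering, rep(1, 3))
  expect_equal(mt$J[1, 2], 1 / 3)
  expect_equal(mt$s[cbind(c(1, 1, 2), c(2, 3, 3))], rep(1, 3))
  # path a-b-c: s(a,c) = 2, b(b) = 1, cc(b) = 0
  pth <- as_test_cin(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  mp <- standard_measures(pth)
  expect_equal(mp$s[1, 3], 2)
  expect_equal(mp$node$betweenness, c(0, 1, 0))
  expect_equal(mp$node$clustering[2], 0)
  # edgeless graph: all-zero conventions
  ed <- standard_measures(as_test_cin(matrix(0, 4, 4)))
  expect_equal(ed$node$degree, rep(0, 4))
  expect_equal(ed$node$clustering, rep(0, 4))
  expect_equal(ed$node$closeness, rep(0, 4))
  expect_true(all(ed$J == 0))
})

test_that("standard measures equal brute-force oracles on 100 random graphs", {
  withr::with_seed(109, {
    for (rep in 1:100) {
      n <- sample(3:8, 1)
      A <- random_adjacency(n, runif(1, 0.15, 0.85))
      m <- standard_measures(as_test_cin(A))
      expect_equal(m$s, oracle_shortest_paths(A), ignore_attr = TRUE)
      expect_equal(m$node$degree, rowSums(A))
      expect_equal(m$node$closeness, oracle_closeness(A))
      expect_equal(m$node$betweenness, oracle_betweenness(A))
      expect_equal(m$node$clustering, oracle_clustering(A))
      expect_equal(m$J, oracle_jaccard(A), ignore_attr = TRUE)
    }
  })
})

test_that("scale-aware measures at beta = 0 are degenerate as expected", {
  withr::with_seed(111, A <- random_adjacency(7, 0.4))
  k <- diffusion_kernel(as_test_cin(A), 0)
  sm <- scale_aware_measures(k)
  expect_equal(sm$node$centrality, rep(0, 7))
  off <- sm$J[upper.tri(sm$J)]
  expect_equal(off, rep(0, 21))
})

test_that("two-node scale-aware centrality matches the closed form", {
  cin <- as_test_cin(rbind(c(0, 1), c(1, 0)))
  for (beta in c(0.24, 1.4)) {
    sm <- scale_aware_measures(diffusion_kernel(cin, beta))
    expect_equal(sm$node$centrality, rep((1 - exp(-2 * beta)) / 2, 2))
  }
})

test_that("scale-aware measures agree with a Taylor-kernel reimplementation", {
  withr::with_seed(113, A <- random_adjacency(8, 0.5))
  beta <- 0.8
  K <- oracle_kernel_taylor(A, beta)
  n <- nrow(A)
  # direct evaluation of the printed formulas
  s_o <- -log(pmax(K, 1e-12))
  J_o <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    J_o[i, j] <- sum(pmin(K[i, ], K[, j])) / sum(pmax(K[i, ], K[, j]))
  }
  c_o <- 1 - diag(K)
  b_o <- vapply(seq_len(n), function(z)
    sum(s_o - outer(s_o[, z], s_o[z, ], "+")) / n^2, numeric(1))
  cc_o <- vapply(seq_len(n), function(x)
    sum(K[x, -x] * J_o[x, -x]), numeric(1))
  sm <- scale_aware_measures(diffusion_kernel(as_test_cin(A), beta))
  expect_equal(sm$s, s_o, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(sm$J, J_o, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(sm$node$centrality, c_o, tolerance = 1e-7)
  expect_equal(sm$node$betweenness, b_o, tolerance = 1e-7)
  expect_equal(sm$node$clustering, cc_o, tolerance = 1e-7)
})

test_that("scale-aware quantities respect their ranges", {
  withr::with_seed(115, A <- random_adjacency(10, 0.3))
  for (beta in c(0.09, 0.8, 6.2)) {
    sm <- scale_aware_measures(diffusion_kernel(as_test_cin(A), beta))
    expect_true(all(sm$s >= 0))
    expect_true(all(sm$J >= 0 & sm$J <= 1 + 1e-12))
    expect_true(all(sm$node$centrality >= 0 & sm$node$centrality < 1))
    expect_true(all(sm$node$clustering >= 0 & sm$node$clustering <= 1 + 1e-9))
  }
})

test_that("link features form the 8-column block", {
  withr::with_seed(117, A <- random_adjacency(6, 0.5))
  cin <- as_test_cin(A)
  m <- standard_measures(cin)
  pairs <- cbind(c(1, 1, 2), c(2, 3, 5))
  lf <- link_features(m, pairs, tag = "std|40000|MAX")
  expect_equal(ncol(lf), 8)
  expect_equal(nrow(lf), 3)
  expect_equal(colnames(lf)[3], "c_absdiff|std|40000|MAX")
  # arithmetic of the node-to-link conversion
  expect_equal(unname(lf[1, "cc_absdiff|std|40000|MAX"]),
               abs(m$node$clustering[1] - m$node$clustering[2]))
  expect_equal(unname(lf[1, "cc_mean|std|40000|MAX"]),
               (m$node$clustering[1] + m$node$clustering[2]) / 2)
  # identical-measure nodes give zero differences
  tri <- standard_measures(as_test_cin(matrix(1, 3, 3) - diag(3)))
  lt <- link_features(tri, cbind(1, 2))
  expect_equal(unname(lt[1, c("c_absdiff", "b_absdiff", "cc_absdiff")]),
               c(0, 0, 0))
})

test_that("feature assembly yields 8 / 80 / 800 columns", {
  withr::with_seed(119, A <- random_adjacency(10, 0.4))
  nodes <- paste0("g", 1:10)
  mk_cin <- function(res, map) {
    structure(list(chrom = "chrT", resolution = res, mapping = map,
                   nodes = nodes,
                   A = `dimnames<-`(A, list(nodes, nodes))),
              class = "cin")
  }
  pairs <- data.frame(geneA = c("g1", "g2"), geneB = c("g5", "g9"))
  one_std <- assemble_features(mk_cin(4e4, "MAX"), pairs, mode = "standard")
  expect_equal(ncol(one_std$X), 8)
  one_stm <- assemble_features(mk_cin(4e4, "MAX"), pairs, mode = "stm")
  expect_equal(ncol(one_stm$X), 80)
  grid <- unlist(lapply(c(40, 80, 120, 160, 200) * 1e3, function(r)
    lapply(c("MAX", "TSS"), function(mp) mk_cin(r, mp))), recursive = FALSE)
  full <- assemble_features(grid, pairs, mode = "stm")
  expect_equal(ncol(full$X), 800)
  expect_false(anyDuplicated(colnames(full$X)) > 0)
  ten_std <- assemble_features(grid, pairs, mode = "standard")
  expect_equal(ncol(ten_std$X), 80)
  expect_true(all(is.finite(full$X)))
})

test_that("node relabeling leaves pairwise features identical", {
  withr::with_seed(121, A <- random_adjacency(9, 0.4))
  nodes <- paste0("g", 1:9)
  cin1 <- as_test_cin(A, nodes)
  perm <- withr::with_seed(122, sample(9))
  cin2 <- as_test_cin(A[perm, perm], nodes[perm])
  pairs <- data.frame(geneA = c("g1", "g3"), geneB = c("g2", "g7"))
  f1 <- assemble_features(cin1, pairs, mode = "both")
  f2 <- assemble_features(cin2, pairs, mode = "both")
  expect_equal(f1$X, f2$X, tolerance = 1e-9)
})
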