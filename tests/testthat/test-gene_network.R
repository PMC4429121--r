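make_norm <- function(scores, bin_size = 4e4, chrom = "chrT") {
  scores <- as.matrix(scores)
  diag(scores) <- 0
  cintopo:::norm_contact(scores, chrom, bin_size, "rank", L = 2 * nrow(scores))
}

test_that("bins_of_gene covers half-open overlaps", {
  expect_equal(bins_of_gene(0, 40000, 40000), 0)
  expect_equal(bins_of_gene(30000, 90000, 40000), 0:2)
  expect_equal(bins_of_gene(79999, 80001, 40000), 1:2)
  # exhaustive overlap oracle on random intervals
  withr::with_seed(9, {
    for (rep in 1:25) {
      s <- sample(0:399999, 1)
      e <- s + sample(1:100000, 1)
      bs <- sample(c(1e4, 4e4), 1)
      oracle <- Filter(function(b) max(s, b * bs) < min(e, (b + 1) * bs),
                       0:ceiling((e + 1) / bs))
      expect_equal(bins_of_gene(s, e, bs), as.integer(oracle))
    }
  })
})

toy_genes <- function() {
  gene_table(gene_id = c("gx", "gy"), chrom = "chrT",
             start = c(40000, 200000), end = c(120000, 240000),
             strand = c("+", "+"))
  # gx bins {1,2}, gy bin {5} at 40 kb
}

test_that("MAX- and TSS-mapping pick the documented cells", {
  s <- matrix(0, 6, 6)
  s[2, 6] <- s[6, 2] <- 3   # c(bin1, bin5)
  s[3, 6] <- s[6, 3] <- 7   # c(bin2, bin5)
  nm <- make_norm(s)
  genes <- toy_genes()
  smax <- map_genes(nm, genes, "MAX")
  expect_equal(smax$scores["gx", "gy"], 7)
  stss <- map_genes(nm, genes, "TSS")
  expect_equal(stss$scores["gx", "gy"], 3)
  expect_true(is.na(smax$scores["gx", "gx"]))
})

test_that("MAX-mapped scores dominate TSS-mapped scores elementwise", {
  nm <- make_norm(withr::with_seed(3, {
    m <- matrix(runif(20^2, 1, 40), 20)
    (m + t(m)) / 2
  }))
  withr::with_seed(4, {
    starts <- sort(sample(seq(0, 7e5, by = 1e4), 10))
    genes <- gene_table(paste0("g", 1:10), "chrT", starts, starts + 60000,
                        sample(c("+", "-"), 10, TRUE))
  })
  smax <- map_genes(nm, genes, "MAX")$scores
  stss <- map_genes(nm, genes, "TSS")$scores
  both <- !is.na(smax) & !is.na(stss)
  expect_true(all(smax[both] >= stss[both]))
})

test_that("same-bin gene pairs are excluded from scores", {
  nm <- make_norm(matrix(2, 3, 3))
  genes <- gene_table(c("a", "b"), "chrT", c(1000, 20000), c(9000, 30000),
                      c("+", "+"))  # both entirely in bin 0
  for (map in c("MAX", "TSS")) {
    s <- map_genes(nm, genes, map)
    expect_true(is.na(s$scores["a", "b"]))
  }
})

test_that("TSS outside the matrix errors", {
  nm <- make_norm(matrix(1, 3, 3))
  genes <- gene_table("far", "chrT", 200000, 260000, "+")
  expect_error(map_genes(nm, genes, "TSS"), "outside")
  expect_error(map_genes(nm, genes, "MAX"), "outside")
})

test_that("minus-strand TSS binning uses the last transcribed base", {
  nm <- make_norm(matrix(1, 3, 3))
  # gene ends exactly on a bin boundary; its TSS coordinate is 80000 but
  # the last transcribed base (79999) is in bin 1
  genes <- gene_table("gm", "chrT", 10000, 80000, "-")
  expect_equal(genes$tss, 80000)
  expect_equal(cintopo:::tss_bin(genes, 4e4), 1L)
})

test_that("genome threshold is the interpolated pooled quantile", {
  mk <- function(vals, chrom) {
    n <- length(vals)
    sc <- matrix(NA_real_, n + 1, n + 1)   # NA = excluded pair
    sc[cbind(1:n, 2:(n + 1))] <- vals
    sc[cbind(2:(n + 1), 1:n)] <- vals
    structure(list(chrom = chrom, resolution = 4e4, mapping = "MAX",
                   genes = paste0(chrom, "_", 0:n), scores = sc),
              class = "gene_score_matrix")
  }
  pool <- mk(1:100, "c1")
  expect_equal(genome_threshold(list(pool), 0.9), 90.1)
  expect_equal(genome_threshold(list(mk(rep(7, 30), "c1"))), 7)
  # pooling is order-invariant across chromosomes
  a <- mk(1:50, "c1"); b <- mk(51:100, "c2")
  expect_equal(genome_threshold(list(a, b), 0.9),
               genome_threshold(list(b, a), 0.9))
  expect_equal(genome_threshold(list(a, b), 0.9), 90.1)
})

test_that("CIN links require strict threshold exceedance", {
  nm <- make_norm(withr::with_seed(8, {
    m <- matrix(runif(12^2, 0, 10), 12); (m + t(m)) / 2
  }))
  withr::with_seed(11, {
    starts <- sort(sample(seq(0, 4e5, by = 2e4), 8))
    genes <- gene_table(paste0("g", 1:8), "chrT", starts, starts + 15000,
                        rep("+", 8))
  })
  s <- map_genes(nm, genes, "MAX")
  top <- max(s$scores, na.rm = TRUE)
  expect_equal(sum(build_cin(s, top)$A), 0)          # strict: no edge at max
  low <- build_cin(s, min(s$scores, na.rm = TRUE) - 1)
  expect_equal(sum(low$A) / 2, sum(!is.na(s$scores[upper.tri(s$scores)])))

  thr <- genome_threshold(list(s), 0.9)
  cin <- build_cin(s, thr)
  brute <- sum(s$scores[upper.tri(s$scores)] > thr, na.rm = TRUE)
  expect_equal(sum(cin$A) / 2, brute)
  # monotone non-increasing in threshold
  edges <- vapply(quantile(s$scores[upper.tri(s$scores)], c(.1, .5, .9),
                           na.rm = TRUE),
                  function(t) sum(build_cin(s, t)$A) / 2, numeric(1))
  expect_true(all(diff(edges) <= 0))
})

test_that("bin-based CIN matches a brute-force supra-threshold count", {
  nm <- make_norm(withr::with_seed(21, {
    m <- matrix(runif(50^2), 50); (m + t(m)) / 2
  }))
  thr <- 0.8
  cin <- build_bin_cin(nm, thr)
  expect_equal(sum(cin$A) / 2, sum(nm$scores[upper.tri(nm$scores)] > thr))
  expect_equal(sum(build_bin_cin(nm, -Inf)$A) / 2, 50 * 49 / 2)

  s3 <- matrix(0, 3, 3); s3[1, 3] <- s3[3, 1] <- 5
  one <- build_bin_cin(make_norm(s3), 1)
  expect_equal(sum(one$A), 2)
  expect_equal(one$A["bin0", "bin2"], 1)
})

test_that("MAX-mapped CIN edges contain TSS-mapped edges at equal threshold", {
  nm <- make_norm(withr::with_seed(31, {
    m <- matrix(runif(25^2, 0, 50), 25); (m + t(m)) / 2
  }))
  withr::with_seed(32, {
    starts <- sort(sample(seq(0, 9e5, by = 2e4), 12))
    genes <- gene_table(paste0("g", 1:12), "chrT", starts, starts + 70000,
                        sample(c("+", "-"), 12, TRUE))
  })
  thr <- 25
  amax <- build_cin(map_genes(nm, genes, "MAX"), thr)$A
  atss <- build_cin(map_genes(nm, genes, "TSS"), thr)$A
  expect_true(all(amax[atss == 1] == 1))
})

test_that("gene order permutation leaves the graph isomorphic", {
  nm <- make_norm(withr::with_seed(41, {
    m <- matrix(runif(20^2, 0, 9), 20); (m + t(m)) / 2
  }))
  withr::with_seed(42, {
    starts <- sort(sample(seq(0, 7e5, by = 2e4), 9))
    genes <- gene_table(paste0("g", 1:9), "chrT", starts, starts + 30000,
                        rep("+", 9))
  })
  perm <- withr::with_seed(43, sample(9))
  c1 <- build_cin(map_genes(nm, genes, "MAX"), 5)
  c2 <- build_cin(map_genes(nm, genes[perm, ], "MAX"), 5)
  expect_equal(c2$A[c1$nodes, c1$nodes], c1$A)
})

test_that("BED6 annotations round-trip", {
  genes <- toy_genes()
  f <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(genes, f)
  back <- read_genes_bed(f)
  expect_equal(back, genes)
})
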