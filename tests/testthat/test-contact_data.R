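test_that("triplet reader mirrors entries and fills missing cells with zero", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0\t1\t5", f)
  m <- read_contact_matrix(f, "triplet", n_bins = 3)
  expect_equal(m$counts[1, 2], 5)
  expect_equal(m$counts[2, 1], 5)
  expect_equal(sum(m$counts), 10)
  expect_equal(m$n_bins, 3)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  m0 <- read_contact_matrix(empty, "triplet", n_bins = 2)
  expect_equal(m0$counts, matrix(0, 2, 2))
})

test_that("reader rejects invalid input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0 1 2 ", "3 4 5", "9 8 7"), f)  # asymmetric dense
  expect_error(read_contact_matrix(f, "dense"), "symmetric")

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0\t5\t3", g)
  expect_error(read_contact_matrix(g, "triplet", n_bins = 3), "range")
  writeLines("0\t1\t-2", g)
  expect_error(read_contact_matrix(g, "triplet", n_bins = 3), "egative")
})

test_that("contact matrices round-trip through the triplet writer", {
  m <- random_contact(12, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(m, f)
  m2 <- read_contact_matrix(f, "triplet", chrom = m$chrom,
                            bin_size = m$bin_size, n_bins = m$n_bins)
  expect_equal(m2$counts, m$counts)
})

test_that("coarsening sums blocks, keeps partial blocks, conserves mass", {
  u <- contact_matrix(matrix(1, 4, 4))
  expect_equal(coarsen(u, 2)$counts, matrix(4, 2, 2))
  expect_equal(coarsen(u, 2)$bin_size, 8e4)

  m <- random_contact(9, seed = 1)
  expect_identical(coarsen(m, 1), m)

  m5 <- random_contact(5, seed = 2)
  c2 <- coarsen(m5, 2)
  expect_equal(c2$n_bins, 3)
  expect_equal(sum(c2$counts), sum(m5$counts))
  # per-cell brute-force block sums
  groups <- list(1:2, 3:4, 5)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(c2$counts[i, j],
                 sum(m5$counts[groups[[i]], groups[[j]], drop = FALSE]))
  }
  expect_error(coarsen(m5, 0), "positive")
})

test_that("rank normalization follows the average-rank tie convention", {
  # pool values [5, 2, 2, 9]: the 5 ranks 3.0, each 2 ranks 1.5
  r <- rank(c(5, 2, 2, 9), ties.method = "average")
  expect_equal(r[1], 3.0)
  expect_equal(r[2:3], c(1.5, 1.5))
  # same convention through the matrix path: 3-bin matrix whose first
  # super-diagonal is [5, 2] pooled with the second [9] and wrap-around
  cm <- contact_matrix(rbind(c(0, 5, 9), c(5, 0, 2), c(9, 2, 0)))
  nm <- rank_normalize(cm, L = 3)
  # pool for m=1 is [5, 2, 9]: ranks 2, 1, 3
  expect_equal(nm$scores[1, 2], 2)
  expect_equal(nm$scores[2, 3], 1)
  expect_equal(nm$scores[1, 3], 3)  # m=2 pool extended with m=1 values ranks 5 in [9,5,2]
  expect_equal(nm$scores, t(nm$scores))
  expect_equal(diag(nm$scores), rep(0, 3))
})

test_that("a strictly increasing super-diagonal pooled at its own length ranks 1..L", {
  n <- 11
  cm <- matrix(0, n, n)
  cm[cbind(1:(n - 1), 2:n)] <- 1:(n - 1)
  cm <- contact_matrix(cm + t(cm))
  nm <- rank_normalize(cm, L = n - 1)
  expect_equal(super_diag <- nm$scores[cbind(1:(n - 1), 2:n)],
               as.numeric(1:(n - 1)))
})

test_that("rank normalization matches a sort-based oracle and stays in [1, L]", {
  m <- random_contact(30, seed = 42)
  L <- 60
  nm <- rank_normalize(m, L)
  off <- nm$scores[upper.tri(nm$scores)]
  expect_true(all(off >= 1 & off <= L))
  # oracle: rebuild each pool independently and rank by explicit sorting
  n <- m$n_bins
  sdvals <- lapply(1:(n - 1), function(k)
    m$counts[cbind(1:(n - k), (1 + k):n)])
  for (k in c(1, 5, 15, 29)) {
    pool <- sdvals[[k]]
    d <- 1
    while (length(pool) < L) {
      lo <- if (k - d >= 1) sdvals[[k - d]] else numeric(0)
      hi <- if (k + d <= n - 1) sdvals[[k + d]] else numeric(0)
      need <- L - length(pool)
      if (length(lo) + length(hi) <= need) {
        pool <- c(pool, lo, hi)
      } else {
        t_lo <- min(length(lo), ceiling(need / 2))
        t_hi <- min(length(hi), need - t_lo)
        t_lo <- min(length(lo), need - t_hi)
        pool <- c(pool, lo[seq_len(t_lo)], hi[seq_len(t_hi)])
      }
      d <- d + 1
    }
    expect_equal(nm$scores[cbind(1:(n - k), (1 + k):n)],
                 oracle_sort_ranks(pool)[seq_len(n - k)])
  }
})

test_that("rank normalization is invariant to monotone transforms and rewards raises", {
  m <- random_contact(20, seed = 7)
  L <- 40
  nm1 <- rank_normalize(m, L)
  m2 <- contact_matrix(m$counts^3 + 2, chrom = m$chrom, bin_size = m$bin_size)
  nm2 <- rank_normalize(m2, L)
  expect_equal(nm1$scores, nm2$scores)
  # raising one raw count never lowers its rank
  m3 <- m$counts
  m3[2, 5] <- m3[2, 5] + 100
  m3[5, 2] <- m3[2, 5]
  nm3 <- rank_normalize(contact_matrix(m3), L)
  expect_gte(nm3$scores[2, 5], nm1$scores[2, 5])
})

test_that("pure distance decay yields tied mid-ranks in fully pooled classes", {
  n <- 12
  d <- abs(outer(1:n, 1:n, "-"))
  cm <- contact_matrix(100 * (1 + d)^-1)
  nm <- rank_normalize(cm, L = n - 1)
  # first super-diagonal is a full pool of its own identical values
  v <- nm$scores[cbind(1:(n - 1), 2:n)]
  expect_true(all(v == (1 + (n - 1)) / 2))
})

test_that("short matrices rescale ranks to span [1, L]", {
  cm <- contact_matrix(rbind(c(0, 3, 1), c(3, 0, 7), c(1, 7, 0)))
  L <- 100
  nm <- rank_normalize(cm, L)  # 3 off-diagonal entries in total
  off <- sort(c(nm$scores[1, 2], nm$scores[2, 3], nm$scores[1, 3]))
  expect_equal(off, c(1, (1 + L) / 2, L))
})

test_that("average normalization divides by the distance mean", {
  cm <- contact_matrix(matrix(5, 4, 4))
  an <- average_normalize(cm)
  expect_equal(an$scores[upper.tri(an$scores)],
               rep(1, 6))
  expect_equal(diag(an$scores), rep(0, 4))

  cm2 <- contact_matrix(rbind(c(0, 2, 0), c(2, 0, 4), c(0, 4, 0)))
  an2 <- average_normalize(cm2)
  expect_equal(an2$scores[1, 2], 2 / 3)
  expect_equal(an2$scores[2, 3], 4 / 3)

  m <- random_contact(15, seed = 3)
  an3 <- average_normalize(m)
  n <- m$n_bins
  for (k in c(1, 4, 9)) {
    expect_equal(mean(an3$scores[cbind(1:(n - k), (1 + k):n)]), 1)
  }
})

test_that("average normalization of pure power-law decay is all ones off-diagonal", {
  n <- 10
  d <- abs(outer(1:n, 1:n, "-"))
  cm <- contact_matrix(50 * (1 + d)^-1.2)
  an <- average_normalize(cm)
  expect_equal(an$scores[upper.tri(an$scores)],
               rep(1, n * (n - 1) / 2))
})

test_that("pool_length is twice the largest chromosome's bin count", {
  mats <- list(random_contact(10, 1), random_contact(25, 2))
  expect_equal(pool_length(mats), 50)
})
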