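#' Binned intra-chromosomal Hi-C contact matrix
#'
#' Container for one chromosome's symmetric matrix of Hi-C contact counts at
#' a fixed bin size.  Bin indices are 0-based; the genomic distance between
#' bins `i` and `j` is `|i - j| * bin_size` base pairs and `m = |i - j|` is
#' the super-diagonal index used by the distance-aware normalizations.
#'
#' @param counts square, symmetric, non-negative numeric matrix of contact
#'   counts (rows/columns indexed by bin).
#' @param chrom chromosome identifier.
#' @param bin_size bin width in base pairs.
#' @return an object of class `contact_matrix` with fields `chrom`,
#'   `bin_size`, `counts` and `n_bins`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", bin_size = 40000) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square", call. = FALSE)
  }
  if (any(counts < 0)) stop("contact counts must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  stopifnot_scalar(bin_size, "bin_size")
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  dimnames(counts) <- NULL
  structure(
    list(chrom = as.character(chrom), bin_size = bin_size,
         counts = counts, n_bins = nrow(counts)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %g bp, total mass %g\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$counts)))
  invisible(x)
}

#' Read a binned contact matrix from text
#'
#' Two plain-text layouts are supported: `"triplet"` rows `i j count` with
#' 0-based bin indices (missing cells are zero; each entry is mirrored so
#' the result is symmetric), and `"dense"`, a square whitespace-delimited
#' matrix which must already be symmetric.
#'
#' @param path file to read.
#' @param format `"triplet"` or `"dense"`.
#' @param chrom chromosome identifier attached to the result.
#' @param bin_size bin width in base pairs.
#' @param n_bins number of bins; required for triplet input whenever the
#'   trailing bins of the chromosome carry no contacts (defaults to the
#'   largest index seen + 1).
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("triplet", "dense"),
                                chrom = "chr1", bin_size = 40000,
                                n_bins = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    if (nrow(m) != ncol(m)) stop("dense contact matrix must be square", call. = FALSE)
    return(contact_matrix(m, chrom = chrom, bin_size = bin_size))
  }
  tri <- utils::read.table(path, header = FALSE,
                           col.names = c("i", "j", "count"),
                           colClasses = c("integer", "integer", "numeric"))
  if (nrow(tri) == 0 && is.null(n_bins)) {
    stop("empty triplet file needs an explicit n_bins", call. = FALSE)
  }
  if (is.null(n_bins)) n_bins <- max(tri$i, tri$j) + 1L
  if (nrow(tri) > 0) {
    if (any(tri$count < 0)) stop("negative counts in triplet input", call. = FALSE)
    if (any(tri$i < 0 | tri$j < 0 | tri$i >= n_bins | tri$j >= n_bins)) {
      stop("bin index out of declared range", call. = FALSE)
    }
  }
  m <- matrix(0, n_bins, n_bins)
  if (nrow(tri) > 0) {
    # mirror each entry; conflicting duplicates for the same unordered pair
    # (after mirroring) are an error
    key <- paste(pmin(tri$i, tri$j), pmax(tri$i, tri$j))
    agg <- tapply(tri$count, key, function(v) length(unique(v)))
    if (any(agg > 1)) {
      stop("conflicting duplicate entries for a bin pair", call. = FALSE)
    }
    m[cbind(tri$i + 1L, tri$j + 1L)] <- tri$count
    m[cbind(tri$j + 1L, tri$i + 1L)] <- tri$count
  }
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}

#' Write a contact matrix in triplet text format
#'
#' Emits one `i<TAB>j<TAB>count` row per non-zero upper-triangle cell
#' (diagonal included), with 0-based indices.
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   count = m$counts[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Lower-resolution matrices are obtained by summing the contact counts of
#' `factor` consecutive bins in each dimension.  A trailing partial block is
#' kept as a smaller block, so total matrix mass is conserved exactly.
#'
#' @param m a [contact_matrix()].
#' @param factor positive integer number of consecutive bins to merge.
#' @return a [contact_matrix()] with `bin_size * factor`.
#' @export
coarsen <- function(m, factor) {
  stopifnot(inherits(m, "contact_matrix"))
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != round(factor)) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(m)
  groups <- (seq_len(m$n_bins) - 1L) %/% factor
  s <- rowsum(m$counts, groups)
  s <- t(rowsum(t(s), groups))
  contact_matrix(s, chrom = m$chrom, bin_size = m$bin_size * factor)
}

#' Normalized Hi-C contact matrix
#'
#' Internal constructor for the result of [rank_normalize()] /
#' [average_normalize()].  `scores` is symmetric; the main diagonal carries
#' no score (stored as 0 and excluded from all downstream use).
#'
#' @keywords internal
norm_contact <- function(scores, chrom, bin_size, method, L = NA_real_) {
  structure(
    list(chrom = chrom, bin_size = bin_size, scores = scores,
         n_bins = nrow(scores), method = method, L = L),
    class = "norm_contact"
  )
}

#' @export
print.norm_contact <- function(x, ...) {
  cat(sprintf("<norm_contact> %s: %d bins of %g bp, %s-normalized%s\n",
              x$chrom, x$n_bins, x$bin_size, x$method,
              if (x$method == "rank") sprintf(" (L = %g)", x$L) else ""))
  invisible(x)
}

# Values of the k-th super-diagonal (k >= 1), in increasing bin-index order.
super_diagonal <- function(counts, k) {
  n <- nrow(counts)
  counts[cbind(seq_len(n - k), seq_len(n - k) + k)]
}

#' Rank-based normalization of a contact matrix
#'
#' Removes genomic distance bias by replacing each contact count with its
#' rank among contacts at a similar genomic distance.  Each cell of
#' super-diagonal `m` (genomic distance `m * bin_size`) is ranked within a
#' pool built from that distance class: the class's own values alone when
#' it holds at least `min_pool` cells, otherwise extended with the
#' neighboring super-diagonals around it — drawing evenly from the `m - d`
#' and `m + d` flanks, nearest `d` first, values in increasing bin-index
#' order — until the pool reaches `min(L, min_pool)`.  Ranks use the
#' average-rank convention for ties and are rescaled linearly so every
#' pool spans the common range `[1, L]`, which is held constant across
#' chromosomes; scores are thereby comparable genome-wide.
#'
#' Pooling across distances is restricted to short (far-from-diagonal)
#' classes, whose count distributions are nearly identical, and the
#' extension draws evenly from both flanks: contact counts decay with
#' distance, so the nearer flank runs systematically high and the farther
#' flank low, and any broader or one-sided pooling measurably
#' re-introduces the distance trend the normalization exists to remove.
#'
#' @param m a [contact_matrix()].
#' @param L rank range (and maximal pool length); conventionally twice the
#'   number of bins of the largest chromosome in the dataset (see
#'   [pool_length()]).
#' @param min_pool smallest distance class ranked on its own; shorter
#'   classes pool their flanking neighbors up to this length.
#' @return a `norm_contact` whose scores lie in `[1, L]` off the diagonal;
#'   the diagonal is excluded (0).
#' @export
rank_normalize <- function(m, L, min_pool = 100) {
  stopifnot(inherits(m, "contact_matrix"))
  stopifnot_scalar(L, "L")
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  n <- m$n_bins
  if (n < 2) stop("cannot normalize a matrix with fewer than 2 bins", call. = FALSE)
  diags <- lapply(seq_len(n - 1L), function(k) super_diagonal(m$counts, k))
  out <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) {
    own <- diags[[k]]
    pool <- own
    target <- min(L, max(length(own), min_pool))
    d <- 1L
    while (length(pool) < target && d <= n - 2L) {
      lo <- if (k - d >= 1L) diags[[k - d]] else numeric(0)
      hi <- if (k + d <= n - 1L) diags[[k + d]] else numeric(0)
      need <- target - length(pool)
      if (length(lo) + length(hi) <= need) {
        pool <- c(pool, lo, hi)
      } else {
        # split the final draw evenly over the two flanks; backfill from
        # the other flank when one is short
        t_lo <- min(length(lo), ceiling(need / 2))
        t_hi <- min(length(hi), need - t_lo)
        t_lo <- min(length(lo), need - t_hi)
        pool <- c(pool, lo[seq_len(t_lo)], hi[seq_len(t_hi)])
      }
      d <- d + 1L
    }
    r <- rank(pool, ties.method = "average")[seq_along(own)]
    np <- length(pool)
    if (np != L) {
      # every pool spans the common range [1, L]
      r <- if (np == 1L) rep((1 + L) / 2, 1L) else 1 + (r - 1) * (L - 1) / (np - 1)
    }
    idx <- cbind(seq_len(n - k), seq_len(n - k) + k)
    out[idx] <- r
    out[idx[, 2:1, drop = FALSE]] <- r
  }
  norm_contact(out, m$chrom, m$bin_size, "rank", L = L)
}

#' Average-based normalization of a contact matrix
#'
#' Divides each contact count by the mean raw count at the same genomic
#' distance (observed / distance-expected).  Distance classes with zero mean
#' yield 0.  The diagonal is excluded (0), as in [rank_normalize()].
#'
#' @param m a [contact_matrix()].
#' @return a `norm_contact` with non-negative scores.
#' @export
average_normalize <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  n <- m$n_bins
  if (n < 2) stop("cannot normalize a matrix with fewer than 2 bins", call. = FALSE)
  out <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) {
    own <- super_diagonal(m$counts, k)
    mu <- mean(own)
    v <- if (mu > 0) own / mu else rep(0, length(own))
    idx <- cbind(seq_len(n - k), seq_len(n - k) + k)
    out[idx] <- v
    out[idx[, 2:1, drop = FALSE]] <- v
  }
  norm_contact(out, m$chrom, m$bin_size, "average")
}

#' Genome-wide rank pool length
#'
#' The pool length `L` shared by all chromosomes: twice the number of bins
#' of the largest chromosome in the dataset at the given resolution.
#'
#' @param mats list of [contact_matrix()] objects (one per chromosome).
#' @return integer pool length.
#' @export
pool_length <- function(mats) {
  stopifnot(length(mats) >= 1)
  2L * max(vapply(mats, function(m) m$n_bins, integer(1)))
}
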