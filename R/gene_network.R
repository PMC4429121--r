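#' Read gene annotations from BED6
#'
#' Columns: chrom, start, end, name, score, strand (0-based half-open
#' coordinates).  The transcription start site is `start` for plus-strand
#' genes and `end` for minus-strand genes.
#'
#' @param path BED6 file.
#' @return a data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_genes_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end",
                                         "name", "score", "strand"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "character"))
  gene_table(gene_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, strand = bed$strand)
}

#' Assemble a validated gene annotation table
#'
#' @param gene_id,chrom,start,end,strand vectors of equal length; `start <
#'   end` (0-based half-open), strand `"+"` or `"-"`.
#' @return a data.frame with a derived `tss` column (`start` on `+`, `end`
#'   on `-`).
#' @export
gene_table <- function(gene_id, chrom, start, end, strand) {
  if (any(start >= end)) stop("gene start must be < end", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (anyDuplicated(gene_id)) stop("duplicated gene ids", call. = FALSE)
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end),
             stringsAsFactors = FALSE)
}

#' Write gene annotations as BED6
#' @param genes a gene annotation data.frame (see [gene_table()]).
#' @param path output file.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bins overlapped by a gene
#'
#' All 0-based bin indices overlapping `[start, end)` under half-open
#' arithmetic at the given bin size.
#'
#' @param start,end gene interval, 0-based half-open, base pairs.
#' @param bin_size bin width in base pairs.
#' @return integer vector of 0-based bin indices.
#' @export
bins_of_gene <- function(start, end, bin_size) {
  stopifnot_scalar(bin_size, "bin_size")
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  if (start >= end) stop("gene start must be < end", call. = FALSE)
  seq.int(floor(start / bin_size), floor((end - 1) / bin_size))
}

# 0-based bin holding a gene's TSS.  The tss *coordinate* is start (+) or
# end (-); for binning, minus-strand genes use their last transcribed base
# (tss - 1), which always lies inside the gene.
tss_bin <- function(genes, bin_size) {
  pos <- ifelse(genes$strand == "+", genes$tss, genes$tss - 1)
  as.integer(floor(pos / bin_size))
}

#' Gene-pair Hi-C score matrix
#'
#' Maps a normalized contact matrix to intra-chromosomal gene pairs.
#' MAX-mapping takes the maximum normalized score among all bin pairs
#' spanned by the two genes; TSS-mapping takes the score of the bin pair
#' holding the two transcription start sites.  Pairs whose score would be a
#' self-contact (identical TSS bin, or no off-diagonal bin combination)
#' carry `NA` and are excluded downstream.
#'
#' @param n a `norm_contact` (see [rank_normalize()]).
#' @param genes gene annotation data.frame; all genes must lie on `n`'s
#'   chromosome and within the matrix range.
#' @param mapping `"MAX"` or `"TSS"`.
#' @return an object of class `gene_score_matrix`: fields `chrom`,
#'   `resolution`, `mapping`, `genes`, and a symmetric `scores` matrix with
#'   `NA` diagonal and `NA` for excluded pairs.
#' @export
map_genes <- function(n, genes, mapping = c("MAX", "TSS")) {
  mapping <- match.arg(mapping)
  stopifnot(inherits(n, "norm_contact"))
  if (!all(genes$chrom == n$chrom)) {
    stop("all genes must be on chromosome ", n$chrom, call. = FALSE)
  }
  nb <- n$n_bins
  ng <- nrow(genes)
  if (mapping == "TSS") {
    tb <- tss_bin(genes, n$bin_size)
    if (any(tb < 0 | tb >= nb)) stop("TSS outside matrix range", call. = FALSE)
    s <- n$scores[tb + 1L, tb + 1L, drop = FALSE]
    s[outer(tb, tb, "==")] <- NA_real_  # identical TSS bin: self-contact
  } else {
    binsets <- lapply(seq_len(ng), function(i) {
      b <- bins_of_gene(genes$start[i], genes$end[i], n$bin_size)
      if (any(b < 0 | b >= nb)) stop("gene outside matrix range", call. = FALSE)
      b + 1L
    })
    s0 <- n$scores
    diag(s0) <- -Inf  # self-contacts never contribute to the max
    rowmax <- function(mat, sets) {
      t(vapply(sets, function(b) {
        if (length(b) == 1L) mat[b, ] else apply(mat[b, , drop = FALSE], 2, max)
      }, numeric(ncol(mat))))
    }
    r1 <- rowmax(s0, binsets)        # gene x bin
    s <- rowmax(t(r1), binsets)      # gene x gene (symmetric since s0 is)
    s <- (s + t(s)) / 2              # kill round-off asymmetry
    s[is.infinite(s)] <- NA_real_    # only self-contact combinations existed
  }
  diag(s) <- NA_real_
  dimnames(s) <- list(genes$gene_id, genes$gene_id)
  structure(
    list(chrom = n$chrom, resolution = n$bin_size, mapping = mapping,
         genes = genes$gene_id, scores = s),
    class = "gene_score_matrix"
  )
}

#' @export
print.gene_score_matrix <- function(x, ...) {
  cat(sprintf("<gene_score_matrix> %s: %d genes, %s-mapping at %g bp\n",
              x$chrom, length(x$genes), x$mapping, x$resolution))
  invisible(x)
}

#' Genome-wide score threshold
#'
#' Empirical quantile (linear interpolation between order statistics) of
#' all gene-pair scores pooled over the given chromosomes, used to decide
#' which interactions become network links.
#'
#' @param score_matrices list of `gene_score_matrix` objects sharing
#'   resolution and mapping (one per chromosome).
#' @param percentile fraction in (0, 1), e.g. `0.9`.
#' @return scalar threshold.
#' @export
genome_threshold <- function(score_matrices, percentile = 0.9) {
  stopifnot(length(score_matrices) >= 1)
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must be in (0, 1)", call. = FALSE)
  }
  res <- unique(vapply(score_matrices, `[[`, numeric(1), "resolution"))
  map <- unique(vapply(score_matrices, `[[`, character(1), "mapping"))
  if (length(res) != 1 || length(map) != 1) {
    stop("score matrices must share resolution and mapping", call. = FALSE)
  }
  pool <- unlist(lapply(score_matrices, function(s) {
    v <- upper_tri_values(s$scores)
    v[!is.na(v)]
  }), use.names = FALSE)
  if (length(pool) == 0) stop("empty score pool", call. = FALSE)
  stats::quantile(pool, percentile, type = 7, names = FALSE)
}

# Internal CIN constructor.
new_cin <- function(A, nodes, chrom, resolution, mapping) {
  dimnames(A) <- list(nodes, nodes)
  structure(
    list(chrom = chrom, resolution = resolution, mapping = mapping,
         nodes = nodes, A = A),
    class = "cin"
  )
}

#' @export
print.cin <- function(x, ...) {
  cat(sprintf("<cin> %s: %d nodes, %d links (%s-mapping at %g bp)\n",
              x$chrom, length(x$nodes), sum(x$A) / 2, x$mapping, x$resolution))
  invisible(x)
}

#' Build a gene-based chromatin interaction network
#'
#' Unweighted undirected graph over the genes of one chromosome: a link is
#' placed between two genes iff their normalized Hi-C score strictly
#' exceeds the threshold.  Isolated genes are retained as nodes.
#'
#' @param s a `gene_score_matrix`.
#' @param threshold scalar, typically from [genome_threshold()].
#' @return an object of class `cin` with fields `nodes` and binary
#'   adjacency `A` (no self-loops).
#' @export
build_cin <- function(s, threshold) {
  stopifnot(inherits(s, "gene_score_matrix"))
  stopifnot_scalar(threshold, "threshold")
  A <- (!is.na(s$scores) & s$scores > threshold) + 0
  diag(A) <- 0
  new_cin(A, s$genes, s$chrom, s$resolution, s$mapping)
}

#' Build a bin-based chromatin interaction network
#'
#' Variant of [build_cin()] whose nodes are the genomic bins themselves
#' (named `bin0`, `bin1`, ...); links join bins whose normalized score
#' strictly exceeds the threshold.  Gene pairs are later placed on this
#' graph through their TSS bins.
#'
#' @param n a `norm_contact`.
#' @param threshold scalar threshold; `-Inf` yields the complete bin graph.
#' @return an object of class `cin` with `mapping = "BIN"`.
#' @export
build_bin_cin <- function(n, threshold) {
  stopifnot(inherits(n, "norm_contact"))
  A <- (n$scores > threshold) + 0
  diag(A) <- 0
  new_cin(A, paste0("bin", seq_len(n$n_bins) - 1L),
          n$chrom, n$bin_size, "BIN")
}

#' Export a CIN as a two-column edge list
#' @param cin a `cin`.
#' @param path output file (tab-delimited node-id pairs).
#' @export
write_cin_edges <- function(cin, path) {
  idx <- which(upper.tri(cin$A) & cin$A == 1, arr.ind = TRUE)
  utils::write.table(
    data.frame(cin$nodes[idx[, 1]], cin$nodes[idx[, 2]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# igraph view of a CIN (used by the standard topological measures).
cin_graph <- function(cin) {
  igraph::graph_from_adjacency_matrix(cin$A, mode = "undirected")
}
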