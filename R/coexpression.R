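#' Read a spatial expression matrix from TSV
#'
#' First column: sample (voxel) id; remaining columns: one per gene,
#' holding expression energy.
#'
#' @param path TSV file with a header row.
#' @return numeric matrix, samples x genes, with sample row names and gene
#'   column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a spatial expression matrix as TSV
#' @param expr samples x genes matrix.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(sample = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-chromosome spatial co-expression matrices
#'
#' Spearman rank correlation between the spatial expression profiles of
#' every intra-chromosomal gene pair (average ranks on ties).  Constant
#' gene columns, for which Spearman correlation is undefined, are dropped
#' with a warning.
#'
#' @param expr samples x genes numeric matrix with gene column names.
#' @param genes_by_chrom named list mapping chromosome id to the gene ids
#'   on it.
#' @return named list of symmetric correlation matrices, one per
#'   chromosome.
#' @export
spearman_coexpression <- function(expr, genes_by_chrom) {
  if (nrow(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene column(s) dropped")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  lapply(genes_by_chrom, function(ids) {
    ids <- intersect(ids, colnames(expr))
    if (length(ids) < 2) stop("fewer than 2 usable genes on a chromosome",
                              call. = FALSE)
    stats::cor(expr[, ids, drop = FALSE], method = "spearman")
  })
}

#' Label gene pairs by co-expression strength
#'
#' Three-way labeling from genome-wide percentiles of all intra-chromosomal
#' Spearman correlations pooled across chromosomes: `strong` above the
#' `pos_pct` percentile (strictly), `none` below the `neg_pct` percentile
#' (strictly), `excluded` in between.  With `pos_pct == neg_pct` the
#' boundary collapses and no pair is excluded (`none` then uses `<=`).
#'
#' @param rhos named list of per-chromosome correlation matrices (see
#'   [spearman_coexpression()]).
#' @param pos_pct,neg_pct percentile fractions, `pos_pct >= neg_pct`.
#' @return object of class `labeled_pairs`: data.frame `pairs` with columns
#'   `chrom`, `geneA`, `geneB`, `rho`, `class`, plus the two `thresholds`.
#' @export
label_pairs <- function(rhos, pos_pct = 0.9, neg_pct = 0.5) {
  if (pos_pct < neg_pct) stop("pos_pct must be >= neg_pct", call. = FALSE)
  per_chrom <- lapply(names(rhos), function(chrom) {
    m <- rhos[[chrom]]
    idx <- upper_tri_pairs(nrow(m))
    data.frame(chrom = chrom,
               geneA = colnames(m)[idx[, 1]],
               geneB = colnames(m)[idx[, 2]],
               rho = m[idx], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, per_chrom)
  thr_pos <- stats::quantile(pairs$rho, pos_pct, type = 7, names = FALSE)
  thr_neg <- stats::quantile(pairs$rho, neg_pct, type = 7, names = FALSE)
  cls <- rep("excluded", nrow(pairs))
  cls[pairs$rho > thr_pos] <- "strong"
  if (pos_pct == neg_pct) {
    cls[pairs$rho <= thr_neg] <- "none"
  } else {
    cls[pairs$rho < thr_neg] <- "none"
  }
  pairs$class <- factor(cls, levels = c("strong", "none", "excluded"))
  structure(list(pairs = pairs,
                 thresholds = c(strong = thr_pos, none = thr_neg)),
            class = "labeled_pairs")
}

#' @export
print.labeled_pairs <- function(x, ...) {
  tab <- table(x$pairs$class)
  cat(sprintf("<labeled_pairs> %d pairs: %d strong / %d none / %d excluded\n",
              nrow(x$pairs), tab[["strong"]], tab[["none"]], tab[["excluded"]]))
  invisible(x)
}

#' Write labeled pairs as TSV
#' @param lp a `labeled_pairs`.
#' @param path output file; columns `chrom geneA geneB rho class`.
#' @export
write_labeled_pairs <- function(lp, path) {
  utils::write.table(lp$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
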