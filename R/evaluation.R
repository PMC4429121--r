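#' Co-localization enrichment of strongly co-expressed pairs
#'
#' One-tailed Wilcoxon rank-sum test of whether strongly co-expressed gene
#' pairs have larger normalized Hi-C scores than pairs without strong
#' co-expression.  Exact p-values are used when the smaller group has at
#' most 20 pairs (and no ties); the tie- and continuity-corrected normal
#' approximation otherwise.
#'
#' @param scores a `gene_score_matrix` (see [map_genes()]).
#' @param labels a `labeled_pairs` object, or its `pairs` data.frame
#'   restricted to the scores' chromosome.
#' @return list: `W` statistic, `p_value` (one-tailed, strong > none),
#'   `minus_log10_p`, `n_strong`, `n_none`.
#' @export
colocalization_test <- function(scores, labels) {
  stopifnot(inherits(scores, "gene_score_matrix"))
  pairs <- if (inherits(labels, "labeled_pairs")) labels$pairs else labels
  pairs <- pairs[pairs$chrom == scores$chrom, , drop = FALSE]
  idx <- cbind(match(pairs$geneA, scores$genes),
               match(pairs$geneB, scores$genes))
  h <- scores$scores[idx]
  strong <- h[pairs$class == "strong" & !is.na(h)]
  none <- h[pairs$class == "none" & !is.na(h)]
  if (length(strong) == 0 || length(none) == 0) {
    stop("both label classes must be non-empty", call. = FALSE)
  }
  use_exact <- min(length(strong), length(none)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(strong, none, alternative = "greater",
                       exact = use_exact, correct = TRUE)
  )
  list(W = unname(wt$statistic), p_value = wt$p.value,
       minus_log10_p = -log10(wt$p.value),
       n_strong = length(strong), n_none = length(none))
}

#' Co-localization scan over chromosomes and resolutions
#'
#' Runs [colocalization_test()] over a grid of gene-pair score matrices and
#' applies a Bonferroni correction whose family size is the number of
#' tests actually performed (chromosomes x resolutions).
#'
#' @param score_grid list of `gene_score_matrix` objects covering the
#'   chromosome x resolution grid (one mapping).
#' @param labels a `labeled_pairs` object.
#' @param alpha family-wise significance level.
#' @return data.frame: `chrom`, `resolution`, `mapping`, `n_strong`,
#'   `n_none`, `W`, `p`, `minus_log10_p`, `significant_after_bonferroni`.
#' @export
colocalization_scan <- function(score_grid, labels, alpha = 0.05) {
  rows <- lapply(score_grid, function(s) {
    ct <- colocalization_test(s, labels)
    data.frame(chrom = s$chrom, resolution = s$resolution,
               mapping = s$mapping, n_strong = ct$n_strong,
               n_none = ct$n_none, W = ct$W, p = ct$p_value,
               minus_log10_p = ct$minus_log10_p)
  })
  out <- do.call(rbind, rows)
  out$significant_after_bonferroni <- out$p < alpha / nrow(out)
  out
}

#' Correlation between Hi-C and co-expression matrices
#'
#' Pearson correlation between the vectorized upper triangles of a
#' gene-pair Hi-C score matrix and the matching Spearman co-expression
#' matrix, over their shared gene universe (pairs with an excluded Hi-C
#' score are dropped).
#'
#' @param hic a `gene_score_matrix`.
#' @param rho symmetric co-expression matrix with gene dimnames.
#' @return Pearson r.
#' @export
matrix_correlation <- function(hic, rho) {
  stopifnot(inherits(hic, "gene_score_matrix"))
  common <- intersect(hic$genes, colnames(rho))
  if (length(common) < 2) stop("fewer than 2 shared genes", call. = FALSE)
  h <- hic$scores[common, common]
  r <- rho[common, common]
  hv <- upper_tri_values(h)
  rv <- upper_tri_values(r)
  keep <- !is.na(hv) & !is.na(rv)
  if (sum(keep) < 2) stop("fewer than 2 scored pairs", call. = FALSE)
  stats::cor(hv[keep], rv[keep], method = "pearson")
}
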