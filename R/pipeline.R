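#' Build the full multi-resolution study object
#'
#' Runs every data-side stage of the pipeline on a dataset bundle: coarsens
#' each chromosome's contact matrix to the requested resolutions,
#' normalizes (rank-based by default, with the pool length shared
#' genome-wide per resolution), maps scores to gene pairs under both
#' MAX- and TSS-mapping, derives the genome-wide score threshold per
#' (resolution, mapping), builds the chromatin interaction networks
#' (plus bin-based CINs at the coarsest resolution), computes Spearman
#' co-expression, and labels gene pairs genome-wide.
#'
#' @param bundle a `synthetic_bundle` (see [generate_dataset()] /
#'   [read_dataset()]), or any list with named fields `contacts` (list of
#'   [contact_matrix()]), `genes` (list of gene annotation data.frames) and
#'   `expression` (samples x genes matrix).
#' @param resolutions bin sizes in bp; must be multiples of the base bin.
#' @param percentile score percentile defining network links.
#' @param pos_pct,neg_pct co-expression label percentiles (see
#'   [label_pairs()]).
#' @param normalization `"rank"` or `"average"`.
#' @param L optional rank-pool length override; by default twice the bin
#'   count of the largest chromosome at each resolution.
#' @return object of class `cin_study` holding normalized matrices, score
#'   matrices, thresholds, CINs, bin CINs, co-expression matrices and
#'   labels.
#' @export
hic_pipeline <- function(bundle,
                         resolutions = c(40, 80, 120, 160, 200) * 1e3,
                         percentile = 0.9, pos_pct = 0.9, neg_pct = 0.5,
                         normalization = c("rank", "average"), L = NULL) {
  normalization <- match.arg(normalization)
  chroms <- names(bundle$contacts)
  stopifnot(length(chroms) >= 1, identical(chroms, names(bundle$genes)))
  base_bin <- unique(vapply(bundle$contacts, `[[`, numeric(1), "bin_size"))
  stopifnot(length(base_bin) == 1)
  resolutions <- sort(resolutions)
  if (any(resolutions %% base_bin != 0)) {
    stop("resolutions must be multiples of the base bin size", call. = FALSE)
  }
  mappings <- c("MAX", "TSS")
  norms <- list(); scores <- list(); thresholds <- list(); cins <- list()
  for (res in resolutions) {
    key <- as.character(res)
    coarse <- lapply(bundle$contacts, coarsen, factor = res %/% base_bin)
    L_res <- if (is.null(L)) pool_length(coarse) else L
    norms[[key]] <- lapply(coarse, function(m) {
      if (normalization == "rank") rank_normalize(m, L_res) else average_normalize(m)
    })
    scores[[key]] <- list(); thresholds[[key]] <- list(); cins[[key]] <- list()
    for (map in mappings) {
      sm <- lapply(chroms, function(ch)
        map_genes(norms[[key]][[ch]], bundle$genes[[ch]], mapping = map))
      names(sm) <- chroms
      thr <- genome_threshold(sm, percentile)
      scores[[key]][[map]] <- sm
      thresholds[[key]][[map]] <- thr
      cins[[key]][[map]] <- lapply(sm, build_cin, threshold = thr)
    }
  }
  # bin-based CINs at the coarsest resolution, thresholded on the pooled
  # bin-level scores across chromosomes
  top <- as.character(max(resolutions))
  bin_pool <- unlist(lapply(norms[[top]], function(n)
    upper_tri_values(n$scores)), use.names = FALSE)
  bin_thr <- stats::quantile(bin_pool, percentile, type = 7, names = FALSE)
  bin_cins <- lapply(norms[[top]], build_bin_cin, threshold = bin_thr)

  genes_by_chrom <- lapply(bundle$genes, `[[`, "gene_id")
  rhos <- spearman_coexpression(bundle$expression, genes_by_chrom)
  labels <- label_pairs(rhos, pos_pct = pos_pct, neg_pct = neg_pct)
  structure(
    list(chroms = chroms, genes = bundle$genes, base_bin = base_bin,
         resolutions = resolutions, percentile = percentile,
         pos_pct = pos_pct, neg_pct = neg_pct,
         normalization = normalization,
         norms = norms, scores = scores, thresholds = thresholds,
         cins = cins, bin_cins = bin_cins, bin_threshold = bin_thr,
         rhos = rhos, labels = labels),
    class = "cin_study"
  )
}

#' @export
print.cin_study <- function(x, ...) {
  cat(sprintf("<cin_study> %d chromosome(s), resolutions %s bp, %s-normalized\n",
              length(x$chroms),
              paste(format(x$resolutions, scientific = FALSE), collapse = "/"),
              x$normalization))
  print(x$labels)
  invisible(x)
}

#' Re-label a study from a different expression matrix
#'
#' Recomputes co-expression and gene-pair labels while reusing every
#' network built by [hic_pipeline()]; used, e.g., to test the pipeline on
#' expression with the co-expression signal switched off.
#'
#' @param study a `cin_study`.
#' @param expression replacement samples x genes matrix.
#' @return the study with new `rhos` and `labels`.
#' @export
relabel_study <- function(study, expression) {
  stopifnot(inherits(study, "cin_study"))
  genes_by_chrom <- lapply(study$genes, `[[`, "gene_id")
  study$rhos <- spearman_coexpression(expression, genes_by_chrom)
  study$labels <- label_pairs(study$rhos, pos_pct = study$pos_pct,
                              neg_pct = study$neg_pct)
  study
}

#' Named feature modes of the classification experiments
#'
#' Translates a mode name into the feature-set parameters understood by
#' [study_features()].  Modes: `direct_link`;
#' `standard_single_max`/`standard_single_tss` (base resolution);
#' `standard_multi_max`/`standard_multi_tss`; `standard_multi_tssmax`;
#' `stm_single_max`/`stm_single_tss`; `stm_multi_max`/`stm_multi_tss`;
#' `stm_multi_tssmax` (the full 800-column set); `bin_standard`;
#' `bin_stm`.
#'
#' @param name mode name.
#' @return list of [study_features()] arguments.
#' @export
feature_mode <- function(name) {
  modes <- list(
    direct_link         = list(sets = "direct"),
    standard_single_max = list(sets = "standard", single = TRUE, mappings = "MAX"),
    standard_single_tss = list(sets = "standard", single = TRUE, mappings = "TSS"),
    standard_multi_max  = list(sets = "standard", mappings = "MAX"),
    standard_multi_tss  = list(sets = "standard", mappings = "TSS"),
    standard_multi_tssmax = list(sets = "standard", mappings = c("MAX", "TSS")),
    stm_single_max      = list(sets = "stm", single = TRUE, mappings = "MAX"),
    stm_single_tss      = list(sets = "stm", single = TRUE, mappings = "TSS"),
    stm_multi_max       = list(sets = "stm", mappings = "MAX"),
    stm_multi_tss       = list(sets = "stm", mappings = "TSS"),
    stm_multi_tssmax    = list(sets = "stm", mappings = c("MAX", "TSS")),
    bin_standard        = list(sets = "standard", bin_based = TRUE),
    bin_stm             = list(sets = "stm", bin_based = TRUE)
  )
  if (!name %in% names(modes)) {
    stop("unknown feature mode: ", name, call. = FALSE)
  }
  modes[[name]]
}

# Gene-pair node indices on a bin-based CIN: each gene is placed on its
# TSS bin; pairs sharing one bin use the degenerate self-pair.
bin_pair_index <- function(study, chrom, pairs) {
  genes <- study$genes[[chrom]]
  res <- max(study$resolutions)
  tb <- tss_bin(genes, res) + 1L
  names(tb) <- genes$gene_id
  cbind(tb[pairs$geneA], tb[pairs$geneB])
}

#' Per-chromosome feature matrices and labels for classification
#'
#' Extracts, for every strong/none labeled gene pair of each chromosome,
#' the feature columns of the requested mode: graph-topological link
#' features of the gene-based CINs (standard and/or scale-aware, over the
#' chosen resolutions and mappings), the single direct-link indicator, or
#' features on the bin-based CIN with genes placed on their TSS bins.
#'
#' @param study a `cin_study`.
#' @param sets `"stm"`, `"standard"`, `"both"`, or `"direct"`.
#' @param mappings subset of `c("MAX", "TSS")`.
#' @param single if TRUE use only the base (finest) resolution.
#' @param bin_based if TRUE use the bin-based CIN at the coarsest
#'   resolution instead of the gene-based CINs.
#' @param betas diffusion-scale schedule for scale-aware blocks.
#' @param centrality centrality slot of the standard blocks.
#' @return named list (per chromosome) of lists with elements `X`
#'   (feature matrix), `y` (logical labels, TRUE = strong), and `pairs`.
#' @export
study_features <- function(study, sets = c("stm", "standard", "both", "direct"),
                           mappings = c("MAX", "TSS"), single = FALSE,
                           bin_based = FALSE, betas = beta_schedule(),
                           centrality = "closeness") {
  sets <- match.arg(sets)
  stopifnot(inherits(study, "cin_study"))
  res_keys <- as.character(if (single) study$resolutions[1] else study$resolutions)
  lab <- study$labels$pairs
  out <- lapply(study$chroms, function(ch) {
    pairs <- lab[lab$chrom == ch & lab$class %in% c("strong", "none"), ,
                 drop = FALSE]
    y <- pairs$class == "strong"
    if (sets == "direct") {
      cin <- study$cins[[as.character(study$resolutions[1])]][["MAX"]][[ch]]
      idx <- cbind(match(pairs$geneA, cin$nodes), match(pairs$geneB, cin$nodes))
      X <- matrix(cin$A[idx], ncol = 1,
                  dimnames = list(NULL, "direct_link"))
    } else if (bin_based) {
      cin <- study$bin_cins[[ch]]
      idx <- bin_pair_index(study, ch, pairs)
      mode <- if (sets == "both") "both" else sets
      blocks <- list()
      if (mode %in% c("standard", "both")) {
        ms <- standard_measures(cin, centrality = centrality)
        tag <- paste("std", format(cin$resolution, scientific = FALSE), "BIN",
                     sep = "|")
        blocks[[length(blocks) + 1L]] <- link_features(ms, idx, tag = tag)
      }
      if (mode %in% c("stm", "both")) {
        eig <- laplacian_eigen(cin)
        for (beta in betas) {
          k <- structure(list(beta = beta, K = kernel_from_eigen(eig, beta)),
                         class = "diffusion_kernel")
          tag <- paste(signif(beta, 3),
                       format(cin$resolution, scientific = FALSE), "BIN",
                       sep = "|")
          blocks[[length(blocks) + 1L]] <-
            link_features(scale_aware_measures(k), idx, tag = tag)
        }
      }
      X <- do.call(cbind, blocks)
    } else {
      cins <- unlist(lapply(res_keys, function(k) study$cins[[k]][mappings]),
                     recursive = FALSE)
      cins <- lapply(cins, `[[`, ch)
      ft <- assemble_features(cins, pairs[, c("geneA", "geneB")],
                              mode = sets, betas = betas,
                              centrality = centrality)
      X <- ft$X
    }
    list(X = X, y = y, pairs = pairs)
  })
  names(out) <- study$chroms
  out
}

#' Run one classification experiment
#'
#' Executes a named feature mode end to end on a dataset bundle (or an
#' already-built `cin_study`): feature extraction for every labeled gene
#' pair, then per-chromosome stratified cross-validation of the
#' random-hidden-layer classifier, reporting fold AUCs per chromosome and
#' their summary across chromosomes.
#'
#' @param x a `synthetic_bundle` or a `cin_study`.
#' @param mode feature mode name (see [feature_mode()]).
#' @param spec classifier specification (see [rnn_spec()]).
#' @param folds cross-validation folds.
#' @param seed seed for fold assignment.
#' @param out_dir optional directory for JSON + TSV reports.
#' @param ... passed to [hic_pipeline()] when `x` is a bundle.
#' @return object of class `experiment_report`: `mode`, `n_features`,
#'   `feature_manifest`, `per_chrom` (list of `cv_result`), `mean_auc` and
#'   `median_auc` across chromosomes (of per-chromosome mean fold AUC),
#'   `seed`.
#' @export
run_experiment <- function(x, mode = "stm_multi_tssmax", spec = rnn_spec(),
                           folds = 10, seed = 1, out_dir = NULL, ...) {
  study <- if (inherits(x, "cin_study")) x else hic_pipeline(x, ...)
  feats <- do.call(study_features, c(list(study = study), feature_mode(mode)))
  per_chrom <- lapply(feats, function(f)
    cross_validate(spec, f$X, f$y, folds = folds, seed = seed))
  chrom_means <- vapply(per_chrom, `[[`, numeric(1), "mean_auc")
  report <- structure(
    list(mode = mode, n_features = ncol(feats[[1]]$X),
         feature_manifest = colnames(feats[[1]]$X),
         folds = folds, seed = seed,
         per_chrom = per_chrom,
         chrom_mean_auc = chrom_means,
         mean_auc = mean(chrom_means),
         median_auc = stats::median(chrom_means)),
    class = "experiment_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(mode = mode, n_features = report$n_features, folds = folds,
           seed = seed,
           per_chrom = lapply(per_chrom, function(cv)
             list(per_fold_auc = cv$per_fold_auc, mean_auc = cv$mean_auc,
                  median_auc = cv$median_auc)),
           mean_auc = report$mean_auc, median_auc = report$median_auc,
           feature_manifest = report$feature_manifest),
      file.path(out_dir, paste0(mode, "_report.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tab <- do.call(rbind, lapply(names(per_chrom), function(ch)
      data.frame(chrom = ch, fold = seq_len(folds),
                 auc = per_chrom[[ch]]$per_fold_auc)))
    utils::write.table(tab, file.path(out_dir, paste0(mode, "_auc.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> mode %s: %d features, mean AUC %.3f (median %.3f) over %d chromosome(s)\n",
              x$mode, x$n_features, x$mean_auc, x$median_auc,
              length(x$per_chrom)))
  invisible(x)
}

#' Co-localization enrichment scan of a study
#'
#' [colocalization_scan()] over every chromosome and resolution of a study
#' for one mapping method, Bonferroni-corrected for the grid size.
#'
#' @param study a `cin_study`.
#' @param mapping `"MAX"` or `"TSS"`.
#' @param alpha family-wise significance level.
#' @return the scan data.frame (see [colocalization_scan()]).
#' @export
study_enrichment <- function(study, mapping = "MAX", alpha = 0.05) {
  grid <- unlist(lapply(as.character(study$resolutions), function(k)
    study$scores[[k]][[mapping]]), recursive = FALSE)
  colocalization_scan(grid, study$labels, alpha = alpha)
}
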