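#!/usr/bin/env Rscript
# Are strongly co-expressed gene pairs co-localized in the contact data?
# One-tailed Wilcoxon rank-sum enrichment of normalized Hi-C scores
# (strong vs none) over every chromosome x resolution, Bonferroni-corrected
# for the grid, plus the direct Pearson correlation between the Hi-C and
# co-expression matrices.

suppressPackageStartupMessages(library(cintopo))

study <- readRDS("scratch/study.rds")

scan <- rbind(study_enrichment(study, mapping = "MAX"),
              study_enrichment(study, mapping = "TSS"))
write.table(scan, "results/03_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(scan, row.names = FALSE)
cat(sprintf("\n%d of %d tests significant after Bonferroni.\n",
            sum(scan$significant_after_bonferroni), nrow(scan)))

rows <- list()
for (res in names(study$scores)) {
  for (map in names(study$scores[[res]])) {
    for (ch in study$chroms) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, resolution = as.numeric(res), mapping = map,
        pearson_r = matrix_correlation(study$scores[[res]][[map]][[ch]],
                                       study$rhos[[ch]]))
    }
  }
}
mc <- do.call(rbind, rows)
write.table(mc, "results/03_matrix_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nHi-C / co-expression matrix correlation spans %.2f..%.2f:\nthe raw pairwise association is modest, which is why the prediction\nstep characterizes each pair by network topology rather than by its\ndirect contact score alone (see 04_prediction.R).\n",
            min(mc$pearson_r), max(mc$pearson_r)))
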