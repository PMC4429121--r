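# cintopo

Predicting spatial gene co-expression from the topology of chromatin
interaction networks.

## The problem

Hi-C experiments measure how often pairs of genomic loci touch in the
nucleus. Genes that are co-regulated tend to be co-localized in 3D — but
the relationship is not one-to-one: two genes can be strongly co-expressed
without ever touching directly, because they sit in the same chromatin
compartment or share interaction partners. `cintopo` builds, from binned
intra-chromosomal Hi-C contact matrices, one *chromatin interaction
network* (CIN) per chromosome per resolution — genes as nodes, links where
the distance-normalized contact score exceeds the genome-wide 90th
percentile — and asks how well the network topology around a gene pair
predicts whether the pair is strongly co-expressed across spatial
expression samples.

The package is aimed at regulatory genomicists who want to go beyond
"contact = co-expression" and quantify how much *indirect*, multi-scale
chromatin structure contributes.

## The method

Every gene pair `(x, y)` is described by eight link features per measure
set: shortest path `s(x,y)`, Jaccard index `J(x,y)`, and `{|Δ|, mean}` of
three node measures (closeness/degree centrality, betweenness, clustering
coefficient). Two families of measures are used:

* **standard** — the classical unweighted-graph definitions;
* **scale-aware** — diffusion analogues evaluated on the kernel
  `K^β = e^{β(A−D)}` (`A` adjacency, `D` degree matrix), e.g.
  `s^β(x,y) = −log K^β(x,y)`, `c^β(x) = 1 − K^β(x,x)`, with the scale `β`
  sweeping a 10-point geometric schedule
  `β = (2^{6b}−1)/(2^6−1)·(10−10⁻⁴)+10⁻⁴`, `b = 0, 1/9, …, 1` —
  from local loop structure (small `β`) to compartment-level structure
  (large `β`).

Concatenated over 5 resolutions (40–200 kb), 2 gene-pair mappings (MAX /
TSS) and 10 scales, each pair gets 800 features. A random-hidden-layer
neural network (hidden weights fixed from a seeded normal, output layer
solved by ridge least squares) is evaluated by stratified 10-fold
cross-validated AUC against labels from the pooled Spearman co-expression
distribution (*strong* above the genome-wide 90th percentile, *none* below
the median). Co-localization itself is tested by a one-tailed Wilcoxon
rank-sum on the normalized Hi-C scores of strong vs none pairs, Bonferroni
corrected over the chromosome × resolution grid.

A seeded synthetic-data module generates the full study inputs — Poisson
contact matrices with power-law distance decay and boosted compartment
blocks, plus an expression matrix whose genes share latent factors within
blocks — so the entire pipeline runs and is validated without any
external download.

## Worked example

```r
library(cintopo)

bundle <- generate_dataset(default_bundle_configs(seed = 1))
study  <- hic_pipeline(bundle)          # networks at 40..200 kb + labels
print(study)
#> <cin_study> 2 chromosome(s), resolutions 40000/80000/120000/160000/200000 bp, rank-normalized
#> <labeled_pairs> 64750 pairs: 6475 strong / 32375 none / 25900 excluded

spec <- rnn_spec(hidden_nodes = 800, seed = 7)
run_experiment(study, mode = "direct_link", spec = spec, folds = 10, seed = 2)
#> <experiment_report> mode direct_link: 1 features, mean AUC 0.579 (median 0.579) over 2 chromosome(s)
run_experiment(study, mode = "stm_multi_tssmax", spec = spec, folds = 10, seed = 2)
#> <experiment_report> mode stm_multi_tssmax: 800 features, mean AUC 0.974 (median 0.974) over 2 chromosome(s)

head(study_enrichment(study, mapping = "MAX"), 2)
#>       chrom resolution mapping n_strong n_none        W p minus_log10_p significant_after_bonferroni
#> chrS1 chrS1      40000     MAX     4364  21554 78221548 0           Inf                         TRUE
#> chrS2 chrS2      40000     MAX     2110  10821 17974032 0           Inf                         TRUE
```
(The planted-block enrichment is so strong that the normal-approximation
p-values underflow to zero at this sample size.)

Reading the numbers: a classifier that only knows whether two genes touch
directly (`direct_link`) is barely better than chance (AUC 0.58), while
the scale-aware multi-resolution topology of the same networks recovers
the planted co-expression structure almost perfectly (AUC 0.97) — the
signal lives in indirect, multi-scale contact structure. The enrichment
scan confirms that strongly co-expressed pairs have significantly higher
contact scores at every chromosome and resolution. The full mode ladder
(`analysis/04_prediction.R`) reproduces the expected ordering:
direct-link 0.58 < standard single-resolution 0.91–0.92 < standard
multi-resolution 0.96 < scale-aware 0.97–0.98.

The numbered scripts under `analysis/` run the complete study — dataset
generation, network construction, enrichment, the classification ladder,
forward feature selection, leave-one-chromosome-out, and a 2D t-SNE map of
feature profiles — writing tables under `results/`.

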