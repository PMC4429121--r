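---
title: "Predicting spatial co-expression from chromatin interaction network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spatial co-expression from chromatin interaction network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cintopo)
```

## The question and the model

Genes that are co-regulated tend to be co-localized in the three-dimensional
conformation of the genome, through chromatin contacts that range from direct
promoter-promoter loops to shared residence in large chromatin compartments.
`cintopo` asks whether the *spatial co-expression* of two genes — the Spearman
correlation of their expression profiles across spatial samples (voxels) —
can be predicted from the *topology* of a chromatin interaction network (CIN)
built from Hi-C contact data, and in particular whether descriptions of that
topology at multiple genomic resolutions and multiple diffusion scales beat
the obvious baseline, the presence or absence of a direct contact.

The pipeline has five data stages, each exposed as package functions and each
validated independently:

1. **Contact matrices.** Binned intra-chromosomal Hi-C counts at a base bin
   size of 40 kb (`contact_matrix()`, `read_contact_matrix()`). Coarser
   resolutions (80-200 kb by default) are produced by summing consecutive
   bins (`coarsen()`), conserving total mass exactly.
2. **Distance normalization.** Contact counts decay strongly with genomic
   distance, so each count is replaced by its rank among counts at similar
   distance (`rank_normalize()`); an observed/expected variant
   (`average_normalize()`) is provided for comparison. Ranks are pooled to a
   fixed genome-wide length `L` so scores are comparable across chromosomes.
3. **Networks.** Normalized scores are mapped to gene pairs either by the
   maximum over all spanned bin pairs (MAX) or by the TSS-holding bin pair
   (TSS) (`map_genes()`). Links are placed where the score strictly exceeds
   the genome-wide 90th percentile at that resolution and mapping
   (`genome_threshold()`, `build_cin()`); a bin-level variant
   (`build_bin_cin()`) is available at the coarsest resolution.
4. **Topology.** Each gene pair is described by eight link features per
   measure set: shortest path `s`, Jaccard index `J`, and the absolute
   difference and mean of three node measures (centrality, betweenness,
   clustering). The standard set uses the classical graph definitions
   (`standard_measures()`); the scale-aware set evaluates diffusion analogues
   on the kernel `K^beta = exp(beta (A - D))` over a 10-point schedule of
   scales (`scale_aware_measures()`, `beta_schedule()`), so that small `beta`
   sees local loop structure and large `beta` sees compartment-level
   structure. Concatenation over 5 resolutions x 2 mappings x 10 scales
   yields 800 features per pair (`assemble_features()`).
5. **Prediction and statistics.** Gene pairs are labeled from the pooled
   distribution of intra-chromosomal Spearman correlations — *strong* above
   the genome-wide 90th percentile, *none* below the median, the middle band
   excluded (`label_pairs()`) — and a random-hidden-layer network classifier
   is evaluated by stratified 10-fold cross-validated AUC (`rnn_spec()`,
   `cross_validate()`). Enrichment of contacts among strongly co-expressed
   pairs is tested by a one-tailed Wilcoxon rank-sum test with Bonferroni
   correction over the chromosome x resolution grid
   (`colocalization_test()`, `study_enrichment()`).

`hic_pipeline()` wires stages 1-3 and the labeling together into a study
object; `run_experiment()` runs any feature mode end to end. The numbered
scripts under `analysis/` are thin narrative drivers over these functions.

## The diffusion kernel and its scale schedule

The kernel `K^beta = exp(beta (A - D))` is the matrix exponential of the
negative graph Laplacian, computed by symmetric eigendecomposition (exact up
to round-off; the result is re-symmetrized and clamped to `[0, 1]` to kill
round-off noise). It is symmetric, doubly stochastic, equal to the identity
at `beta = 0`, and converges to uniformity over each connected component as
`beta` grows — all of which are asserted in the test suite, alongside
agreement with an independent truncated-Taylor-series implementation.

The scale schedule places 10 values of `beta` geometrically between 0.0001
and 10 via `beta = (2^(6b) - 1)/(2^6 - 1) * (10 - 0.0001) + 0.0001` with `b`
stepping uniformly from 0 to 1: scales concentrate near zero, where the
kernel changes fastest.

```{r}
round(beta_schedule(), 4)
```

Two conventions make the scale-aware features finite everywhere: kernel
entries are floored at `1e-12` before the log (so pairs in different
components get the cap `-log(1e-12)` rather than infinity), and the
scale-aware betweenness is used exactly as defined (it may be negative; no
sign correction is applied).

## Conventions for the standard measures

Graph measures on sparse thresholded networks hit degenerate cases
constantly, so the conventions are fixed and tested:

* Shortest paths are measured in **edges**; unreachable pairs take the
  finite cap `N` (the node count), which exceeds any realizable distance.
  The same cap feeds the closeness sums.
* Closeness of an **isolated node** is 0 (the capped-sum rule alone would
  give `1/(N (N-1))`, an arbitrary positive value for a node with no
  information; zero states the truth more plainly and keeps the edgeless
  graph fully degenerate).
* Betweenness is shortest-path betweenness with all-geodesic counting and
  endpoints excluded; clustering uses the open neighborhood; the Jaccard
  index uses open neighborhoods.
* The "centrality" slot of the eight link features defaults to closeness —
  its scale-aware analogue `1 - K(x,x)` is closeness-like — with degree
  available via the `centrality` argument.
* Pairs are featurized whether or not they are network links, so the
  labeled-pair universe never loses rows.

## Rank normalization: keeping the ranks distance-free

The `m`-th super-diagonal holds all contacts at genomic distance `m` bins.
Each cell is ranked within its own distance class whenever that class holds
at least `min_pool` (default 100) values; shorter classes — the far
super-diagonals, whose count distributions are nearly identical anyway —
are extended with their neighbors, drawing **evenly from the two flanks**
`m - d` and `m + d`, nearest `d` first. All ranks are then rescaled
linearly onto the common range `[1, L]` (by default `L` is twice the bin
count of the largest chromosome), so normalized scores are comparable
across chromosomes and a single genome-wide link threshold is meaningful.

Both restrictions on pooling are load-bearing, and both were adopted after
measuring the alternatives on pure-decay (structure-free) data:

* *Even flank draws.* Counts decay with distance, so the nearer flank runs
  systematically high and the farther flank low. Extending pools by whole
  nearest super-diagonals one at a time leaves each pool dominated by the
  single nearer flank; cells are ranked against mostly-larger values and
  the mean normalized score acquires a strong artificial distance trend
  (measured mean ranks ranged from ~0.27 L to ~0.73 L across distances).
* *Own-class ranking for long diagonals.* Even balanced pools keep two
  residual artifacts: the `m = 1` class has no lower flank and ranks high,
  and a convexity effect leaves a mild gradient. Ranking each sufficiently
  long class purely against itself makes the mean normalized score exactly
  the midpoint `(1 + L)/2` at every distance.

Because strongly co-expressed gene pairs are also genomically close — in
real data and in the generator alike — any residual distance trend in the
scores leaks straight into the co-localization statistics and the
classifier; with these rules the scores carry no distance information
beyond what the contact structure itself provides. One caveat remains even
so: in *shallow* contact data the far distance classes are mostly tied
zeros, whose averaged ranks form a low step that interacts with
MAX-mapping (a maximum over near-continuous ranks is systematically larger
than one over stepped ranks). The synthetic defaults therefore emulate
deeply sequenced data (`contact_scale = 2000`, keeping expected counts
above ~3 at the farthest distances); with sparse real matrices the same
caveat applies to any rank-based normalization.

A chromosome whose entire upper triangle is smaller than `L` pools
everything; a super-diagonal already longer than `L` (only possible with a
user-supplied small `L`) is ranked on itself and rescaled like any other
pool. The
diagonal (self-contacts) is never ranked and never scored: gene pairs whose
score would be a self-contact (identical TSS bin, or no off-diagonal bin
combination under MAX) are excluded from scores, thresholds, links and
enrichment tests. They are *not* excluded from the labeled-pair universe
used for classification, where their features are well-defined graph
quantities; on the bin-based CIN such pairs sit on one node and use the
degenerate self-pair (`s = 0`, `J = 1`, zero differences).

For minus-strand genes the TSS coordinate is the gene end (half-open), but
the TSS *bin* is taken from the last transcribed base (`end - 1`), which
always lies inside the gene; otherwise a gene ending exactly on a bin
boundary would be assigned a bin it does not touch.

## The classifier

The "random neural network" here is a single-hidden-layer feed-forward
network whose input-to-hidden weights are drawn once from a seeded standard
normal and never trained; only the output layer is fit, by ridge-regularized
least squares against +/-1 targets on sigmoid activations of z-scored
features (the z-scoring statistics come from the training fold only). This
choice makes training a single deterministic linear solve — seconds on tens
of thousands of pairs with 800 hidden nodes — and is the classical
random-projection realization of a one-hidden-layer network trained at the
output. The ridge default `1e-3` is there purely to condition the solve;
results are insensitive to it over several orders of magnitude because the
hidden layer is wide. Defaults: 800 hidden nodes (the full feature-set
width), 100 for forward selection; stratified seeded folds because positives
are ~10% of the pooled pairs against ~50% negatives; AUC as the only
reported metric, being threshold-free.

Forward selection evaluates candidate features on a seeded stratified 25%
validation split held out *inside* each outer training fold, adds the best
feature while validation AUC improves, and scores the selected set on the
outer test fold. A full inner cross-validation per candidate would multiply
the cost substantially without changing what is being tested — the ordering
of candidate features under a small-capacity classifier.

## What the synthetic generator emulates — and what it does not

The generator plants the premise the pipeline is meant to detect.
Contacts: `E[c_ij] = s0 (1 + |i-j|)^(-alpha)` times `block_boost` within
one of `n_blocks` contiguous compartment blocks and `type_boost` between
different blocks of the same (alternating) compartment type, with Poisson
counts — Poisson because contacts are small non-negative integers and the
rank normalization is distribution-free anyway. Expression: each sample
draws one latent factor per block and a weaker one (weight 0.5) per
compartment type, and gene `g` mixes its block and type factors with weight
`signal` against independent noise. Same-block pairs therefore have both
boosted contacts (at all distances, exercising small diffusion scales) and
elevated Spearman correlation; same-type cross-block pairs add long-range
structure that only larger scales and coarser resolutions can see.

Default study conditions, chosen once: two chromosomes (24 Mb / 300 genes
and 16 Mb / 200 genes — a few hundred genes per chromosome, the scale of
real per-chromosome gene networks), 40 kb base bins, decay exponent 1,
eight blocks per chromosome (3 Mb and 2 Mb blocks — domain-sized), block
boost 6, type boost 2, 200 spatial samples, signal 0.7, noise SD 1, contact
scale 2000 (deep coverage; see the normalization section for why depth
matters to rank pools). Gene lengths are log-normal around 30 kb, packed
without overlap with exponential gaps.

What passing on this generator shows: the full chain — normalization,
mapping, thresholding, kernels, features, classifier — recovers planted
co-localization/co-expression structure and reports chance when the signal
is absent (label permutation, `signal = 0`) or when the contact structure is
absent (`block_boost = type_boost = 1`). What it does not show: performance
on real Hi-C (experimental bias structure, polymer physics, cell-type
mixtures) or real expression atlases (spatial autocorrelation of voxels,
probe noise); the generator has no inter-chromosomal contacts, no
length-varying gene density, and its compartments are exact contiguous
blocks. Numbers obtained here do not transfer to real data — only the
qualitative ordering of feature modes is expected to.

## Numerical and design choices

* Quantiles everywhere use linear interpolation between order statistics
  (R type 7); "exceeds" is always strict. Ties sitting exactly on a
  threshold are excluded rather than arbitrarily assigned, except in the
  collapsed labeling (`pos_pct == neg_pct`), where *none* takes the boundary
  so that no pair is excluded.
* Label percentiles pool intra-chromosomal pairs genome-wide — the only
  pairs the pipeline ever scores.
* The Wilcoxon enrichment test is exact when the smaller group has at most
  20 pairs (and ties permit), normal with tie and continuity correction
  otherwise; the Bonferroni family is the number of tests actually run.
* t-SNE (`embed_2d()`) is implemented in the package (no installed R t-SNE
  exists in this stack): exact gradient, perplexity calibration by
  bisection, PCA pre-reduction (50 components by default), early
  exaggeration, and PCA-based initialisation with a small seeded jitter.
  Rows with identical feature profiles are collapsed before the gradient
  flow and share one embedded point — coincident points cannot be kept
  together numerically by the (locally repulsive) dynamics, and identical
  profiles deserve identical coordinates anyway. The PCA initialisation
  keeps cluster-level structure reproducible across seeds; per-point
  coordinates still vary with the seed, as they do in any t-SNE.
* All randomness is drawn under locally seeded RNG that restores the
  caller's state, so library calls never perturb user-level reproducibility;
  every generator, fold assignment, and hidden-weight draw is deterministic
  given its seed.

## Problem sizes used by the packaged experiments

The packaged tests and the analysis drivers run the full pipeline on the
default two-chromosome dataset above (about 26,000 and 13,000 labeled pairs
with 800 features), cross-validate with 10 folds, and run forward selection
on the 80-column single-resolution feature set with a 12-feature cap —
sizes chosen so the complete suite executes in a few minutes on an
ordinary machine while still exercising every stage at realistic
per-chromosome scale.

## Known limitations

* In shallow contact data (far-distance classes dominated by tied zero
  counts) rank scores develop a stepped distribution whose interaction with
  MAX-mapping slightly over-scores close gene pairs; the packaged synthetic
  data avoids this by emulating deep coverage, but it is a property of
  rank normalization on sparse matrices generally.
* Scale-aware betweenness can be negative and is kept as defined; it is a
  feature, not a centrality in the axiomatic sense.
* The classifier trains only its output layer; a full backpropagation
  variant would change absolute AUCs little on these feature widths but is
  not provided.
* Inter-chromosomal contacts, bias correction of raw Hi-C reads, and
  expression-atlas preprocessing (voxel masking, probe-to-gene mapping) are
  out of scope; inputs are assumed bias-corrected and gene-mapped.
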