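---
title: "Methods: scoring gene-tissue functional relevance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring gene-tissue functional relevance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fugue)
```

## The problem and the model

Most genes are expressed at physiological levels in most tissues, yet only a
subset are *functionally relevant* there — their inactivation produces a
tissue-level phenotype. The conventional proxy is tissue-specific expression
(the mean z-score of a gene's expression in a tissue after standardizing
each gene across all samples), but specificity is neither necessary nor
sufficient for relevance. This package scores every (gene, tissue) pair by
combining fourteen features in a supervised classifier:

**Expression features** (per gene, over the samples of one tissue):
mean, median, sample SD, coefficient of variation (CV = SD/mean), median
absolute deviation from the median (MADM), expression breadth (fraction of
the tissue's samples in which the gene exceeds its median expression), and
the mean pooled z-score. Low within-tissue variability is itself a signal:
genes whose products a tissue depends on tend to be expressed robustly
across individuals, so CV enters the model alongside the location features.

**Network features** (per gene, on the tissue-projected interactome):
degree, betweenness centrality, local clustering coefficient, numbers of
kinase and transcription-factor neighbors, and the neighbor means of the
z-score and breadth features. The tissue projection retains an edge
between two genes only if both are simultaneously expressed above their
own pooled median (across all samples of all tissues) in at least 25% of
the tissue's samples — an edge survives where the interaction is
plausibly realized in that tissue.

**Classifier.** A gradient-boosted tree ensemble (binary logistic
objective) with shallow trees (`max_depth = 3`), 100 rounds at learning
rate 0.1, and positive instances weighted 10x in the objective to offset
the roughly 1:10 positive:negative imbalance of curated gold sets. Missing
feature values (a gene absent from the network, CV undefined at zero mean)
are routed natively by the tree learner and never imputed — absence from
the tissue network is informative in its own right.

**Labels.** Positives are (gene, tissue) pairs connected through a
disease: a disease mapped to the tissue and to the gene. Negatives are
pairs whose protein is not detected in that tissue. Everything else is
unlabeled and receives a score from the trained model. P takes precedence
over N when the two rules collide (curated disease evidence outweighs
absence of detection); conflicts are counted and reported.

## Scoring without leakage

Three evaluation regimes are implemented, each guarding a different
boundary:

* `repeated_cv()` — stratified 5-fold cross-validation repeated
  independently (default 100 repeats; repeat *r* derives its folds and
  model seed from `seed + r`), reporting fold-pooled auROC and auPRC per
  repeat. The random-classifier expectation of auPRC equals the positive
  prevalence, which is why prevalence is reported alongside.
* `loo_pair_scores()` — every labeled pair is scored by a model trained
  with **all** labeled rows of that gene held out, so a gene's score in one
  tissue never benefits from its own labels in another. Unlabeled pairs are
  scored by the full model.
* `leave_one_tissue_out()` — a whole tissue's rows are excluded from
  training and then scored, testing whether the model captures
  tissue-transferable structure rather than tissue idiosyncrasies.

Normalized ranks are computed within each tissue as
`rank(score, ties = average) / n`, lying in (0, 1] with 1 the top gene, so
ranks are comparable across tissues of different gene counts.

## Evaluation statistics

auROC is computed by the Mann–Whitney identity with average ranks (tied
pairs count 1/2); auPRC by step integration of the precision–recall curve,
processing tied scores as a block so a constant score yields exactly the
prevalence. Both agree with brute-force pair counting, which the test
suite checks on inputs up to 200 items.

Per-feature discrimination (`feature_discrimination()`) reports a
two-sided Wilcoxon rank-sum p-value, auROC/auPRC using the raw feature as
the score (auto-oriented so auROC >= 0.5, with the orientation flagged),
class means, and the pos/neg mean ratio. Wilcoxon tests use R's standard
switching rule (exact below 50 observations without ties, otherwise the
normal approximation with continuity correction).

Because negatives are defined by absent protein detection, their z-score
distribution could differ from positives' for reasons unrelated to
function. `zscore_matched_subsample()` draws negatives without replacement
from quantile bins of the positives' z-score distribution (largest-
remainder apportionment over 20 bins by default) so that model performance
can be re-estimated on z-matched data; bins with insufficient negatives
are reported as shortfall. `compare_to_zscore_baseline()` runs the direct
contest: per tissue, a paired Wilcoxon on the positives' normalized ranks
under the model ordering versus the plain z-score ordering.

## Downstream statistics

* **Trait enrichment.** `map_snps_to_genes()` links a gene to a trait if
  an intragenic SNP (0-based, half-open locus) has association p below
  1e-10, keeping traits with at least 5 genes; `set_enrichment()` then
  tests the overlap of trait genes with the top 10% of a tissue's ranking
  by a two-sided Fisher exact test on the scored-gene universe. The
  reported odds ratio is the sample OR (ad)/(bc), and a result "passes" at
  OR > 1.5 and p < 0.05.
* **Linear clustering.** For a gene set G, members are ordered per
  chromosome by start coordinate and segmented into maximal runs with
  successive starts no more than 500 kb apart; runs of 5 or more (3 as the
  sensitivity variant) are clusters, and the statistic is the fraction *f*
  of G covered by clusters. Significance comes from
  `permutation_null()`: 1000 random gene sets of identical size and
  per-chromosome composition drawn from the annotated universe, with
  z-score and the add-one empirical p `(1 + #{null >= obs}) / (1 + n)` —
  never exactly zero at finite resamples.
* **TAD coverage.** A gene belongs to the topologically associating
  domain containing its start coordinate (TAD sets must be
  non-overlapping). The statistic is the number of distinct TADs holding
  at least `min_genes_per_tad` members of G; fewer TADs for a fixed set
  size means tighter packing, so the permutation test is lower-tailed.
* **TF-overlap dendrograms.** Per tissue the top 20 transcription factors
  by score; tissue distance 1 − Jaccard of the two sets; Ward linkage on
  that distance matrix, exported as Newick.

## The synthetic study generator

`generate_study()` builds a complete study with known ground truth:
log-normal expression with gene-level (SD 1.0 in log space) and
tissue-level (SD 0.3) random effects and sample noise (SD 0.5); planted
positives shifted up by `z_shift = 2` pooled log-SD units in their tissue
with noise SD scaled by `cv_ratio = 0.5`; an Erdős–Rényi interactome
(mean degree 6) where each positive gains `hub_boost = 10` extra edges,
preferentially to TF/kinase nodes; ten tissue-1 positives laid out 100 kb
apart on chromosome 1 inside shared 1 Mb TADs while background genes sit
1.2 Mb apart; values below the 5th percentile set to zero so breadth and
the edge rule see zero inflation. Defaults are 4 tissues × 20 samples,
300 genes, 15 positives and 150 negatives per tissue — a labeled
prevalence of 0.091, matching the imbalance the class weighting is built
for. Effect sizes are deliberately strong: the generator exists to verify
that the pipeline recovers signal it is pointed at, not to imitate any
particular dataset's marginals.

What it does **not** emulate: realistic expression marginals or
correlation structure, scale-free interactome topology, gene-density
heterogeneity along chromosomes, or label noise. Passing recovery tests
therefore demonstrates correctness of the machinery, not expected
performance on real tissue atlases.

## Numerical choices and degenerate inputs

* SD uses the sample (n−1) denominator throughout; breadth uses strict
  inequality against the tissue-level median (ties at the median count as
  not above), with a pooled-median variant behind
  `breadth_median = "pooled"` — the per-tissue reading keeps breadth
  centered near 0.5, which is how it behaves in practice.
* The edge-retention rule is *joint* (both genes above their medians in
  the same samples); a marginal variant is selectable. The joint reading
  encodes co-expression, which is what a realized interaction requires.
* Betweenness uses exact pair normalization (no sampling); clustering
  coefficient is defined as 0 for degree < 2. Genes in the expression
  matrix but outside the network get missing network features, not zeros.
* CV at zero mean is missing, not 0 or infinity.
* Ties in top-k selections (top fraction, top TFs) break by gene id, so
  every ranking artifact is reproducible byte for byte.
* Ward linkage (`ward.D2`) is applied to the 1 − Jaccard matrix directly;
  Jaccard distances satisfy the metric axioms, which the tests verify.
* The per-tissue null of the TAD count degenerates for small gene sets
  when `min_genes_per_tad = 2`: random sets essentially never place two
  members in one TAD, so the count is 0 under the null and positive for a
  planted cluster, which inverts the lower-tail logic. At desk scale the
  covering count (`min_genes_per_tad = 1`) is the meaningful lower-tail
  statistic; both are exposed.
* One root seed drives everything; derived stages use fixed offsets
  (`seed + r` per CV repeat, named offsets in the pipeline), keeping every
  output reproducible and every derived seed within integer range.

## Problem sizes

Test and acceptance runs use the generator defaults (300 genes × 4 tissues,
660 labeled pairs), 10–20 CV repeats, 200–1000 permutation resamples, and
calibration universes of 200 genes; these sizes give stable statistics
(CV auROC SD under 0.01, permutation-p uniformity detectable at KS level
0.01) while keeping a full run in minutes on one core. The defaults
(`n_repeats = 100`, `n_resamples = 1000`) match the method's intended
study-scale operation.

## Known limitations

Tissue projection and feature computation assume the expression matrix is
already normalized to comparable units across samples; no normalization,
batch correction, or identifier mapping is attempted. Exact betweenness on
interactomes beyond ~10^5 edges is expensive (minutes, not hours, per
tissue). The gold-set assembly consumes pre-digested disease→tissue,
disease→gene and detection tables; parsing primary databases is out of
scope. Scores are probabilities under the trained model but are not
calibrated; ranks, not raw scores, are the intended interface for
downstream analyses.
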