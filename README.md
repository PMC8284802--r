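# fugue

Prioritizing tissue-relevant genes from multi-sample expression and a
protein-interaction network.

## The problem

Most genes are expressed in any given tissue, but only some are
*functionally relevant* there — knocking them out produces a tissue-level
phenotype. The standard shortcut, ranking genes by tissue-specific
expression (the mean z-score of a gene standardized across all samples),
misses genes that are moderately expressed yet essential. `fugue` scores
every (gene, tissue) pair by combining 14 features in a class-weighted
gradient-boosted tree classifier:

- **7 expression features** per gene over a tissue's samples: mean,
  median, SD, CV (SD/mean), median absolute deviation from the median,
  expression breadth (fraction of samples above the gene's median), and
  the mean pooled z-score;
- **7 network features** on the tissue-projected interactome (an edge is
  kept when both endpoint genes are above their pooled median expression
  in ≥ 25% of the tissue's samples): degree, betweenness centrality,
  clustering coefficient, kinase- and TF-neighbor counts, and neighbor
  means of z-score and breadth.

Training labels come from a curated gold set: positives are gene–tissue
pairs linked through a disease (disease→tissue plus disease→gene),
negatives are pairs whose protein is undetected in the tissue, everything
else is unlabeled and gets scored. The classifier uses depth-3 trees with
a logistic objective and weights positives 10× to offset the ~1:10 class
imbalance. Leave-one-gene-out refits give every labeled pair a score from
a model that never saw that gene's labels, and a leave-one-tissue-out
regime tests cross-tissue transfer.

The package is aimed at computational biologists with a genes × samples
expression matrix (TPM-like units), a sample→tissue map, and an edge list
— it covers the full path from raw inputs to per-tissue ranked gene
lists, evaluation statistics, and downstream analyses (trait–tissue Fisher
enrichment, linear-genome clustering with a chromosome-matched permutation
null, TAD-coverage statistics, TF-overlap tissue dendrograms in Newick).

## Worked example

A fully synthetic study with planted tissue-relevant genes exercises every
stage without any external data:

```r
library(fugue)

study <- generate_study(sim_config(seed = 1))
ft <- merge(feature_table(study$expression, study$network, study$flags),
            study$labels, by = c("gene", "tissue"))

cv <- repeated_cv(ft, fugue_params(seed = 1), n_repeats = 10)
sprintf("auROC %.3f +/- %.3f, auPRC %.3f +/- %.3f",
        cv$auROC_mean, cv$auROC_sd, cv$auPRC_mean, cv$auPRC_sd)
#> "auROC 0.999 +/- 0.000, auPRC 0.993 +/- 0.002"

scores <- loo_pair_scores(ft, fugue_params(seed = 1))
head(scores[order(scores$tissue, -scores$score), ], 5)
#>   gene tissue label     score normalized_rank
#>  G0165     T1     P 0.9994605       1.0000000
#>  G0213     T1     P 0.9994183       0.9966667
#>  G0217     T1     P 0.9993901       0.9933333
#>  G0079     T1     P 0.9993805       0.9900000
#>  G0270     T1     P 0.9993799       0.9866667
```

The planted positives (label `P`) recover the top of each tissue's
ranking; `normalized_rank` is the within-tissue rank scaled to (0, 1] with
1 = best. With the generator's strong planted effects the cross-validated
auROC is near 1; the interesting checks are the *null* ones (shuffled
labels give auPRC ≈ the 0.091 prevalence — see the acceptance script
below). Split-count feature importances identify the planted signal
carriers:

```r
sort(feature_importances(fugue_train(ft, fugue_params(seed = 1))),
     decreasing = TRUE)[1:5]
#>               CV Centrality_coeff           ZScore           Degree          MeanExp
#>               69               57               43               38                7
```

Low within-tissue variability (CV) and network position carry signal
alongside the conventional z-score, which is the point of an integrative
model.

The same flow runs from one config: `run_pipeline(run_config(seed = 1))`
writes the feature table, labels, score table, evaluation TSVs,
cluster/TAD statistics, a Newick tissue dendrogram, and a `manifest.json`
into an output directory, reproducibly for a given seed. A thin CLI
(`inst/scripts/fugue.R`) wraps `simulate` and `run` for shell use. Real
data enter through `read_expression()` (TSV/GCT 1.2), `read_edge_list()`,
`read_bed()` (gene annotation and TADs), `read_gmt()`, and
`assemble_gold_set()`.

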