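test_that("top-fraction selection is deterministic under ties", {
  st <- data.frame(gene = sprintf("g%03d", 1:100), tissue = "T1",
                   score = rep(0.5, 100), stringsAsFactors = FALSE)
  expect_equal(select_top_fraction(st, "T1", 0.10),
               sprintf("g%03d", 1:10))  # tie broken by gene id
  st$score <- seq(1, 0.01, length.out = 100)
  expect_length(select_top_fraction(st, "T1", 0.10), 10)
  expect_length(select_top_fraction(st, "T1", 1.0), 100)
  expect_error(select_top_fraction(st, "T1", 0), "frac")
  expect_error(select_top_fraction(st, "T1", 1.5), "frac")
})

test_that("SNP-to-gene mapping respects threshold and half-open loci", {
  ann <- gene_annotation(data.frame(gene_id = c("gA", "gB"),
                                    chrom = "chr1",
                                    start = c(100, 300), end = c(200, 400)))
  snp <- data.frame(chrom = "chr1",
                    pos = c(150, 150, 200, 305, 310, 320, 330, 340),
                    p = c(1e-12, 1e-8, 1e-12, rep(1e-12, 5)),
                    trait = c("t1", "t1", "t1", rep("t2", 5)))
  # t1: only the p=1e-12 SNP at 150 counts (200 is outside the half-open
  # locus, 1e-8 fails the threshold) -> 1 gene, below min_genes
  out <- map_snps_to_genes(snp, ann, p_max = 1e-10, min_genes = 1)
  expect_equal(out$t1, "gA")
  expect_equal(out$t2, "gB")
  out5 <- map_snps_to_genes(snp, ann, p_max = 1e-10, min_genes = 2)
  expect_null(out5$t1)
})

test_that("Fisher enrichment reproduces hand-computed odds ratios", {
  s <- sets_from_counts(8, 92, 12, 888)
  e <- set_enrichment(s$query, s$target, s$universe)
  expect_equal(e$odds_ratio, (8 * 888) / (92 * 12), tolerance = 1e-12)
  expect_equal(e$odds_ratio, 6.434783, tolerance = 1e-6)
  expect_true(e$pass)

  s2 <- sets_from_counts(20, 30, 80, 870)
  e2 <- set_enrichment(s2$query, s2$target, s2$universe)
  expect_equal(e2$odds_ratio, 7.25, tolerance = 1e-12)

  # overlap equal to the independence expectation: OR = 1
  s3 <- sets_from_counts(10, 90, 90, 810)
  expect_equal(set_enrichment(s3$query, s3$target, s3$universe)$odds_ratio, 1)

  # zero-cell handling
  s4 <- sets_from_counts(5, 0, 3, 92)
  e4 <- set_enrichment(s4$query, s4$target, s4$universe)
  expect_true(is.infinite(e4$odds_ratio) && e4$zero_cell)
  expect_error(set_enrichment("x", "x", character(0)), "universe")
})

test_that("Fisher p agrees with the hypergeometric oracle", {
  # exhaustive over small tables, random over larger ones
  tables <- list()
  for (n in 4:12) for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b))
    tables[[length(tables) + 1]] <- c(a, b, cc, n - a - b - cc)
  set.seed(33)
  for (i in 1:150) {
    n <- sample(13:50, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tables[[length(tables) + 1]] <- c(cuts[1], cuts[2] - cuts[1],
                                      cuts[3] - cuts[2], n - cuts[3])
  }
  for (tb in tables) {
    a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
    if (a + b + cc + d == 0) next
    if (a + b == 0 || cc + a == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, cc, d), 2))$p.value
    expect_equal(p_pkg, brute_fisher_p(a, b, cc, d), tolerance = 1e-9,
                 info = paste(tb, collapse = ","))
  }
})

test_that("genomic clusters follow the run-and-gap definition", {
  mk_ann <- function(starts, chrom = "chr1")
    gene_annotation(data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                               chrom = chrom, start = starts,
                               end = starts + 1e4))
  # 5 genes 400 kb apart: one cluster, f = 1
  ann <- mk_ann(seq(0, by = 4e5, length.out = 5))
  r <- genomic_clusters(ann$gene_id, ann, min_genes = 5, max_gap = 5e5)
  expect_equal(r$f, 1.0)
  expect_length(r$clusters, 1)

  # 5 genes on 5 chromosomes: f = 0
  ann2 <- gene_annotation(data.frame(gene_id = sprintf("g%02d", 1:5),
                                     chrom = paste0("chr", 1:5),
                                     start = 0, end = 1e4))
  expect_equal(genomic_clusters(ann2$gene_id, ann2, 5, 5e5)$f, 0)

  # 6 genes split 3+3 by one 600 kb gap
  ann3 <- mk_ann(c(0, 4e5, 8e5, 14e5, 18e5, 22e5))
  expect_equal(genomic_clusters(ann3$gene_id, ann3, 5, 5e5)$f, 0)
  expect_equal(genomic_clusters(ann3$gene_id, ann3, 3, 5e5)$f, 1.0)

  # unannotated genes are dropped and counted
  r4 <- genomic_clusters(c(ann$gene_id, "ghost"), ann, 5, 5e5)
  expect_equal(r4$n_unannotated, 1L)
})

test_that("cluster fraction equals the exhaustive segmentation oracle", {
  ann <- calibration_annotation()
  set.seed(44)
  for (i in 1:25) {
    g <- sample(ann$gene_id, sample(5:20, 1))
    for (mg in c(3, 5)) {
      expect_equal(genomic_clusters(g, ann, mg, 5e5)$f,
                   brute_cluster_fraction(g, ann, mg, 5e5),
                   info = paste("draw", i, "min_genes", mg))
    }
  }
  # widening the gap can only increase f
  g <- sample(ann$gene_id, 30)
  f_vals <- sapply(c(1e5, 3e5, 5e5, 1e6), function(gap)
    genomic_clusters(g, ann, 3, gap)$f)
  expect_true(all(diff(f_vals) >= 0))
})

test_that("permutation null flags a planted cluster and is reproducible", {
  ann <- calibration_annotation()
  f_stat <- function(g) genomic_clusters(g, ann, min_genes = 5,
                                         max_gap = 5e5)$f
  # 10 adjacent genes on chr1 plus 5 scattered ones
  planted <- c(ann$gene_id[ann$chrom == "chr1"][11:20],
               ann$gene_id[c(60, 110, 160, 190, 199)])
  r <- permutation_null(f_stat, planted, ann, n_resamples = 300, seed = 2,
                        tail = "upper")
  expect_gt(r$z, 2)
  expect_lt(r$empirical_p, 0.05)
  r2 <- permutation_null(f_stat, planted, ann, n_resamples = 300, seed = 2,
                         tail = "upper")
  expect_identical(r[c("z", "empirical_p")], r2[c("z", "empirical_p")])
  expect_gt(r$empirical_p, 0)  # add-one rule: never exactly zero

  # chromosome-matched draws preserve the per-chromosome composition
  comp_stat <- function(g) {
    tab <- table(ann$chrom[match(g, ann$gene_id)])
    sum(abs(as.numeric(tab[paste0("chr", 1:4)]) -
              c(12, 1, 1, 1)), na.rm = TRUE)
  }
  comp_set <- c(ann$gene_id[ann$chrom == "chr1"][1:12],
                ann$gene_id[c(60, 110, 160)])
  rc <- permutation_null(comp_stat, comp_set, ann, n_resamples = 50,
                         seed = 3, tail = "upper")
  expect_equal(rc$null_sd, 0)  # every draw matches the composition exactly
  expect_equal(rc$null_mean, 0)
})

test_that("TAD coverage counts domains by gene-start membership", {
  tads <- tad_set(data.frame(chrom = "chr1",
                             start = c(0, 1000, 2000),
                             end = c(1000, 2000, 3000)))
  ann <- gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    chrom = "chr1", start = c(100, 900, 1100, 1900, 5000),
    end = c(150, 950, 1150, 1950, 5050)))
  r <- tad_coverage(c("g1", "g2", "g3", "g4"), tads, ann,
                    min_genes_per_tad = 2)
  expect_equal(r$n_tads, 2L)
  expect_equal(r$n_uncovered, 0L)

  # all genes outside every TAD
  r2 <- tad_coverage("g5", tads, ann, min_genes_per_tad = 1)
  expect_equal(r2$n_tads, 0L)
  expect_equal(r2$n_uncovered, 1L)

  # threshold semantics on a single-member TAD
  r3a <- tad_coverage(c("g1", "g2", "g3"), tads, ann, min_genes_per_tad = 1)
  r3b <- tad_coverage(c("g1", "g2", "g3"), tads, ann, min_genes_per_tad = 2)
  expect_equal(r3a$n_tads - r3b$n_tads, 1L)
})

test_that("TF-overlap tissue distances behave like 1 - Jaccard", {
  tfs <- sprintf("tf%02d", 1:40)
  mk_scores <- function(tissue, ranked_tfs)
    data.frame(gene = ranked_tfs, tissue = tissue,
               score = seq(1, 0.1, length.out = length(ranked_tfs)),
               stringsAsFactors = FALSE)
  st <- rbind(mk_scores("A", tfs[1:20]),
              mk_scores("B", tfs[1:20]),          # identical top-20
              mk_scores("C", tfs[11:30]),         # shares 10 of 20
              mk_scores("D", tfs[21:40]))         # disjoint from A
  dd <- tissue_tf_dendrogram(st, tfs, top_k = 20)
  expect_equal(dd$dist["A", "B"], 0)
  expect_equal(dd$dist["A", "C"], 1 - 10 / 30)
  expect_equal(dd$dist["A", "D"], 1)
  expect_true(isSymmetric(dd$dist))
  expect_equal(unname(diag(dd$dist)), rep(0, 4))
  # triangle inequality on all triples
  ts <- rownames(dd$dist)
  for (i in ts) for (j in ts) for (k in ts)
    expect_lte(dd$dist[i, j], dd$dist[i, k] + dd$dist[k, j] + 1e-12)
  # Newick export parses back to the same tips
  tree <- ape::read.tree(text = dd$newick)
  expect_setequal(tree$tip.label, ts)
})
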