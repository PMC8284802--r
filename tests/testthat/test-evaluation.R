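test_that("auROC/auPRC closed-form cases", {
  expect_equal(auroc_auprc(c(1, 0, 1, 0), c(1, 0, 1, 0)),
               c(auROC = 1, auPRC = 1))
  # constant scores: tie convention gives 0.5 / prevalence
  expect_equal(auroc_auprc(rep(0.3, 10), rep(c(1, 0), c(3, 7))),
               c(auROC = 0.5, auPRC = 0.3))
  # hand-counted concordant pairs: 3 of 4 -> 0.75
  m <- auroc_auprc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(unname(m["auROC"]), 0.75)
  expect_error(auroc_auprc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auROC equals brute-force pair counting, with and without ties", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(unname(auroc_auprc(s, y)["auROC"]), brute_auroc(s, y),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("feature discrimination orients, tests, and handles degeneracy", {
  ft <- planted_feature_table(n_pos = 30, n_neg = 120, shift = 50,
                              informative = "ZScore", seed = 2)
  ft$MAD <- as.numeric(ft$label == "P") + 1  # perfect separator, neg mean 1
  ft$Breadth <- 0.5                          # constant
  d <- feature_discrimination(ft)
  mad <- d[d$feature == "MAD", ]
  expect_equal(mad$auROC, 1.0)
  expect_equal(mad$effect_size, 2)
  bre <- d[d$feature == "Breadth", ]
  expect_equal(bre$wilcoxon_p, 1)
  expect_equal(bre$auROC, 0.5)
  # auto-orientation: plant a feature that is LOWER in positives
  ft$CV <- rnorm(nrow(ft)) - 3 * (ft$label == "P")
  d2 <- feature_discrimination(ft)
  cv <- d2[d2$feature == "CV", ]
  expect_true(cv$flipped)
  expect_gt(cv$auROC, 0.95)
})

test_that("rank-sum statistic matches exhaustive enumeration on a toy", {
  pos <- c(2, 3, 4); neg <- c(1, 1, 2)
  w <- suppressWarnings(wilcox.test(pos, neg))$statistic
  # enumerate all pos x neg comparisons: W = #(pos > neg) + 0.5 #(ties)
  w_brute <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(unname(w), w_brute)
})

test_that("null features show uniform p-values at nominal type-I rate", {
  set.seed(77)
  n_sims <- 400
  pv <- replicate(n_sims, {
    x <- rnorm(60); y <- rnorm(60)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  })
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("per-tissue rank test reduces to the exact tail on full separation", {
  st <- data.frame(gene = paste0("g", 1:5), tissue = "T1",
                   label = c("P", "P", "P", "N", "N"),
                   score = c(0.9, 0.8, 0.7, 0.2, 0.1))
  st <- add_normalized_ranks(st)
  r <- rank_tests(st)
  # all P above all N: one-sided p = 1 / choose(5, 3)
  expect_equal(r$per_tissue$p, 1 / choose(5, 3))
})

test_that("per-gene paired rank test pools mean rank differences", {
  set.seed(14)
  genes <- sprintf("g%02d", 1:12)
  st <- expand.grid(gene = genes, tissue = c("T1", "T2", "T3"),
                    stringsAsFactors = FALSE)
  # gene i is positive in tissue (i mod 3) + 1 and negative elsewhere, and
  # scores high only in its positive tissue, so each tissue mixes 4 high-
  # scoring positives with 8 low-scoring negatives
  home <- paste0("T", (match(st$gene, genes) %% 3) + 1)
  st$label <- ifelse(st$tissue == home, "P", "N")
  st$score <- runif(nrow(st), 0, 0.4) + ifelse(st$label == "P", 1, 0)
  st <- add_normalized_ranks(st)
  r <- rank_tests(st)
  expect_equal(nrow(r$per_gene), 12L)
  expect_true(all(r$per_gene$diff > 0))
  expect_lt(r$paired_p, 0.01)

  # a gene with equal ranks in P and N tissues contributes difference 0
  st2 <- data.frame(gene = "g", tissue = c("T1", "T2"),
                    label = c("P", "N"), score = c(0.5, 0.5),
                    normalized_rank = c(0.5, 0.5))
  r2 <- rank_tests(st2)
  expect_equal(r2$per_gene$diff, 0)
})

test_that("matched subsampling reproduces the positive histogram when it can", {
  set.seed(15)
  pos <- runif(100)                  # uniform over bins
  neg <- rep(pos, each = 10) + 1e-9  # 10x negatives in every bin
  out <- zscore_matched_subsample(neg, pos, n_bins = 10, seed = 3)
  expect_equal(unname(out$achieved), unname(out$target))
  expect_equal(sum(out$achieved), length(pos))
  expect_equal(out$shortfall, 0)
  # same seed -> identical subsample
  out2 <- zscore_matched_subsample(neg, pos, n_bins = 10, seed = 3)
  expect_identical(out$indices, out2$indices)

  # matching never worsens the KS distance on the matched feature
  set.seed(16)
  pos2 <- rnorm(200, 1)
  neg2 <- rnorm(2000, -0.5)
  m <- suppressWarnings(  # sparse upper-tail bins legitimately fall short
    zscore_matched_subsample(neg2, pos2, n_bins = 20, seed = 4))
  d_before <- suppressWarnings(ks.test(neg2, pos2)$statistic)
  d_after <- suppressWarnings(ks.test(neg2[m$indices], pos2)$statistic)
  expect_lte(unname(d_after), unname(d_before))

  # empty bin with positive mass warns and reports the shortfall
  expect_warning(
    res <- zscore_matched_subsample(rep(0.05, 50), c(rep(0.1, 5), rep(0.9, 5)),
                                    n_bins = 2, seed = 5),
    "available")
  expect_gt(res$shortfall, 0)
})

test_that("z-score baseline comparison detects direction and ties", {
  set.seed(17)
  n <- 30
  ft <- data.frame(gene = sprintf("g%02d", 1:n), tissue = "T1",
                   ZScore = rnorm(n), stringsAsFactors = FALSE)
  st <- data.frame(gene = ft$gene, tissue = "T1",
                   label = rep(c("P", "N"), c(8, n - 8)),
                   score = ft$ZScore, stringsAsFactors = FALSE)
  # identical orderings -> p = 1, direction 0
  cmp <- compare_to_zscore_baseline(st, ft)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$direction, 0)
  # model strictly better on positives: give positives top scores
  st2 <- st
  st2$score <- rank(st$score) / n + 10 * (st2$label == "P")
  cmp2 <- compare_to_zscore_baseline(st2, ft)
  expect_equal(cmp2$direction, 1)
  expect_lt(cmp2$p, 0.05)
  # positives sit at the top of the z ordering; a model anti-correlated
  # with z must rank them worse -> direction flips, one-sided p large
  ft3 <- ft
  ft3$ZScore <- c(rnorm(8, 5), rnorm(n - 8))
  st3 <- data.frame(gene = ft$gene, tissue = "T1",
                    label = st$label, score = -ft3$ZScore,
                    stringsAsFactors = FALSE)
  cmp3 <- compare_to_zscore_baseline(st3, ft3)
  expect_equal(cmp3$direction, -1)
  expect_gt(cmp3$p, 0.5)
})
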