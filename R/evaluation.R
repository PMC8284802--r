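# Evaluation statistics: auROC via the Mann-Whitney identity, auPRC by
# precision-recall step integration, per-feature discrimination, per-tissue
# and per-gene rank tests, distribution-matched negative subsampling, and
# the comparison against plain z-score ranking.

#' auROC and auPRC of a score vector against binary labels
#'
#' auROC uses the Mann-Whitney identity with average ranks, so tied scores
#' contribute 1/2 per tied positive-negative pair. auPRC integrates the
#' precision-recall curve stepwise, processing tied scores as one block
#' (trapezoid within a block), which makes a constant score give exactly
#' the prevalence.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or "P"/"N").
#' @return named numeric vector `c(auROC =, auPRC =)`.
#' @export
auroc_auprc <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # PR: step integration over score blocks from high to low; a tied block
  # contributes its own precision over its whole recall increment, so a
  # constant score yields exactly the prevalence.
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  blocks <- cumsum(!duplicated(ss))
  tp_block <- tapply(ys, blocks, sum)
  n_block <- tapply(ys, blocks, length)
  tp <- cumsum(tp_block); nn <- cumsum(n_block)
  prec <- tp / nn
  rec <- tp / n1
  prev_rec <- c(0, head(rec, -1))
  auprc <- sum((rec - prev_rec) * prec)
  c(auROC = auroc, auPRC = auprc)
}

.as_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    if (!all(l %in% c("P", "N"))) stop("character labels must be 'P'/'N'")
    as.integer(l == "P")
  } else as.integer(as.logical(labels))
}

#' Per-feature discrimination between positive and negative pairs
#'
#' For each of the 14 features: two-sample Wilcoxon rank-sum p-value
#' (two-sided), auROC/auPRC using the raw feature as the score
#' (auto-oriented so auROC >= 0.5), class means, and effect size
#' pos_mean / neg_mean (NA when neg_mean = 0). Rows with a missing feature
#' value are dropped for that feature. A constant feature reports p = 1 and
#' auROC = 0.5.
#'
#' @param features labeled feature table (P/N rows used).
#' @return data.frame: feature, wilcoxon_p, auROC, auPRC, neg_mean,
#'   pos_mean, effect_size, flipped (TRUE when orientation was reversed).
#' @export
feature_discrimination <- function(features) {
  lab <- .labeled(features)
  y <- .as_binary(lab$label)
  rows <- lapply(feature_names(), function(f) {
    v <- lab[[f]]
    ok <- !is.na(v)
    vi <- v[ok]; yi <- y[ok]
    pos_mean <- mean(vi[yi == 1]); neg_mean <- mean(vi[yi == 0])
    if (length(unique(vi)) < 2) {
      return(data.frame(feature = f, wilcoxon_p = 1, auROC = 0.5,
                        auPRC = mean(yi), neg_mean = neg_mean,
                        pos_mean = pos_mean,
                        effect_size = if (neg_mean != 0) pos_mean / neg_mean else NA_real_,
                        flipped = FALSE))
    }
    p <- suppressWarnings(
      wilcox.test(vi[yi == 1], vi[yi == 0], exact = FALSE)$p.value)
    m <- auroc_auprc(vi, yi)
    flipped <- m[["auROC"]] < 0.5
    if (flipped) m <- auroc_auprc(-vi, yi)
    data.frame(feature = f, wilcoxon_p = p,
               auROC = m[["auROC"]], auPRC = m[["auPRC"]],
               neg_mean = neg_mean, pos_mean = pos_mean,
               effect_size = if (neg_mean != 0) pos_mean / neg_mean else NA_real_,
               flipped = flipped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-tissue and per-gene rank tests on a score table
#'
#' Per tissue (having both classes): one-sided Wilcoxon rank-sum test that
#' positives' normalized ranks exceed negatives'. Per gene (having at least
#' one positive and one negative tissue): the gene's mean rank in positive
#' tissues minus its mean rank in negative tissues, pooled across genes
#' with a one-sided paired Wilcoxon signed-rank test.
#'
#' @param score_table a score table with gene, tissue, label,
#'   normalized_rank.
#' @param alternative passed to the underlying tests (default "greater").
#' @return list with `per_tissue` (tissue, n_pos, n_neg, p), `per_gene`
#'   (gene, mean_pos_rank, mean_neg_rank, diff), `paired_p`, and `skipped`
#'   (tissues lacking both classes).
#' @export
rank_tests <- function(score_table, alternative = "greater") {
  st <- score_table[score_table$label %in% c("P", "N"), , drop = FALSE]
  per_tissue <- list(); skipped <- character(0)
  for (t in unique(st$tissue)) {
    sub <- st[st$tissue == t, , drop = FALSE]
    pos <- sub$normalized_rank[sub$label == "P"]
    neg <- sub$normalized_rank[sub$label == "N"]
    if (!length(pos) || !length(neg)) { skipped <- c(skipped, t); next }
    p <- suppressWarnings(
      wilcox.test(pos, neg, alternative = alternative)$p.value)
    per_tissue[[t]] <- data.frame(tissue = t, n_pos = length(pos),
                                  n_neg = length(neg), p = p)
  }
  per_tissue <- if (length(per_tissue)) do.call(rbind, per_tissue)
                else data.frame(tissue = character(), n_pos = integer(),
                                n_neg = integer(), p = numeric())
  rownames(per_tissue) <- NULL

  per_gene <- list()
  for (g in unique(st$gene)) {
    sub <- st[st$gene == g, , drop = FALSE]
    pos <- sub$normalized_rank[sub$label == "P"]
    neg <- sub$normalized_rank[sub$label == "N"]
    if (!length(pos) || !length(neg)) next
    per_gene[[g]] <- data.frame(gene = g, mean_pos_rank = mean(pos),
                                mean_neg_rank = mean(neg),
                                diff = mean(pos) - mean(neg))
  }
  per_gene <- if (length(per_gene)) do.call(rbind, per_gene)
              else data.frame(gene = character(), mean_pos_rank = numeric(),
                              mean_neg_rank = numeric(), diff = numeric())
  rownames(per_gene) <- NULL
  paired_p <- if (nrow(per_gene) >= 2 && any(per_gene$diff != 0)) {
    suppressWarnings(wilcox.test(per_gene$mean_pos_rank,
                                 per_gene$mean_neg_rank,
                                 paired = TRUE,
                                 alternative = alternative)$p.value)
  } else NA_real_
  list(per_tissue = per_tissue, per_gene = per_gene, paired_p = paired_p,
       skipped = skipped)
}

#' Subsample negatives to match the positives' distribution of one feature
#'
#' Bins the positives' values into `n_bins` quantile bins and draws
#' negatives without replacement per bin, proportional to the positives'
#' bin mass, totalling `n_out`. Bins with positive mass but no available
#' negatives are skipped with a warning and the shortfall reported.
#'
#' @param negatives numeric feature values of negative pairs.
#' @param positives numeric feature values of positive pairs.
#' @param n_bins number of quantile bins (default 20).
#' @param n_out target subsample size (default `length(positives)`).
#' @param seed RNG seed.
#' @return list: `indices` (into `negatives`), `target` and `achieved`
#'   per-bin counts, `shortfall`.
#' @export
zscore_matched_subsample <- function(negatives, positives, n_bins = 20,
                                     n_out = length(positives), seed = 1L) {
  brk <- unique(quantile(positives, probs = seq(0, 1, length.out = n_bins + 1)))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  pos_bin <- cut(positives, brk, include.lowest = TRUE)
  neg_bin <- cut(negatives, brk, include.lowest = TRUE)
  mass <- as.numeric(table(pos_bin)) / length(positives)
  # largest-remainder apportionment of n_out over bins
  raw <- mass * n_out
  target <- floor(raw)
  rem <- n_out - sum(target)
  if (rem > 0) {
    extra <- order(raw - target, decreasing = TRUE)[seq_len(rem)]
    target[extra] <- target[extra] + 1
  }
  set.seed(seed)
  idx <- integer(0); achieved <- integer(length(target))
  lev <- levels(pos_bin)
  for (b in seq_along(lev)) {
    avail <- which(neg_bin == lev[b])
    take <- min(target[b], length(avail))
    if (take < target[b])
      warning(sprintf("bin %s: wanted %d negatives, only %d available",
                      lev[b], target[b], length(avail)))
    if (take > 0) idx <- c(idx, sample(avail, take))
    achieved[b] <- take
  }
  list(indices = sort(idx),
       target = setNames(target, lev), achieved = setNames(achieved, lev),
       shortfall = sum(target) - sum(achieved))
}

#' Compare model ranks with plain z-score ranks on the positives
#'
#' Per tissue with >= 2 positives, ranks every scored gene of the tissue
#' once by the model score and once by the ZScore feature, and runs a
#' paired Wilcoxon signed-rank test on the positives' normalized ranks
#' under the two orderings.
#'
#' @param score_table score table (gene, tissue, label, score).
#' @param features feature table supplying the `ZScore` column for the same
#'   pairs.
#' @param alternative default "greater": model ranks exceed z-score ranks.
#' @return data.frame: tissue, n_pos, mean_model_rank, mean_zscore_rank,
#'   direction (+1 model better, -1 worse, 0 tied), p. Tissues with < 2
#'   positives are skipped.
#' @export
compare_to_zscore_baseline <- function(score_table, features,
                                       alternative = "greater") {
  zmap <- setNames(features$ZScore,
                   paste(features$gene, features$tissue, sep = "\r"))
  st <- as.data.frame(score_table)
  st$ZScore <- zmap[paste(st$gene, st$tissue, sep = "\r")]
  rows <- list()
  for (t in unique(st$tissue)) {
    sub <- st[st$tissue == t & !is.na(st$ZScore), , drop = FALSE]
    pos <- sub$label == "P"
    if (sum(pos) < 2) next
    r_model <- rank(sub$score, ties.method = "average") / nrow(sub)
    r_z <- rank(sub$ZScore, ties.method = "average") / nrow(sub)
    d <- r_model[pos] - r_z[pos]
    p <- if (all(d == 0)) 1 else suppressWarnings(
      wilcox.test(r_model[pos], r_z[pos], paired = TRUE,
                  alternative = alternative)$p.value)
    rows[[t]] <- data.frame(tissue = t, n_pos = sum(pos),
                            mean_model_rank = mean(r_model[pos]),
                            mean_zscore_rank = mean(r_z[pos]),
                            direction = sign(mean(d)), p = p)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(tissue = character(), n_pos = integer(),
                         mean_model_rank = numeric(),
                         mean_zscore_rank = numeric(),
                         direction = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}
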