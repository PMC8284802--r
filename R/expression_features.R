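# Expression-derived features. Seven per (gene, tissue): mean, median, SD,
# CV, MADM, expression breadth, and the mean pooled z-score over the
# tissue's samples. SD uses the sample (n-1) denominator throughout.

#' Pool-standardize each gene's expression across all samples
#'
#' Per gene, subtracts the pooled mean over every sample of every tissue and
#' divides by the pooled sample SD. Genes with zero pooled SD are assigned
#' z = 0 in all samples and recorded in the `zero_sd_genes` attribute.
#'
#' @param em an [expression_matrix()].
#' @return numeric matrix of z-scores, same dimnames as `em$values`, with
#'   attribute `zero_sd_genes`.
#' @export
pooled_zscore <- function(em) {
  v <- em$values
  if (ncol(v) < 2) stop("pooled z-score needs >= 2 samples")
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  zero <- s == 0
  s[zero] <- 1  # avoid 0/0; rows are centered so they become exactly 0
  z <- (v - mu) / s
  attr(z, "zero_sd_genes") <- rownames(v)[zero]
  z
}

#' Expression features for every gene in one tissue
#'
#' For the tissue's sample vector x of a gene:
#' MeanExp = mean(x); MedianExp = median(x); SDofExp = sd(x) (n-1);
#' CV = SDofExp/MeanExp (NA when MeanExp = 0);
#' MAD = median(|x - median(x)|) (MADM, unscaled);
#' Breadth = fraction of tissue samples with x strictly above the median
#' (per-tissue median by default; pooled across all samples when
#' `breadth_median = "pooled"`);
#' ZScore = mean over tissue samples of the pooled per-gene z-score.
#'
#' @param em an [expression_matrix()].
#' @param tissue tissue label present in `em`.
#' @param breadth_median `"tissue"` (default) or `"pooled"`: which median the
#'   Breadth comparison uses.
#' @param z optional precomputed [pooled_zscore()] matrix (avoids recompute
#'   across tissues).
#' @return data.frame with columns gene, tissue and the 7 feature columns.
#' @export
tissue_expression_features <- function(em, tissue,
                                       breadth_median = c("tissue", "pooled"),
                                       z = NULL) {
  breadth_median <- match.arg(breadth_median)
  smp <- tissue_samples(em, tissue)
  if (length(smp) < 2) stop("tissue ", tissue, " has < 2 samples")
  x <- em$values[, smp, drop = FALSE]
  if (is.null(z)) z <- pooled_zscore(em)

  mean_exp <- rowMeans(x)
  median_exp <- apply(x, 1, median)
  sd_exp <- apply(x, 1, sd)
  cv <- ifelse(mean_exp > 0, sd_exp / mean_exp, NA_real_)
  madm <- apply(x, 1, function(r) median(abs(r - median(r))))
  breadth_ref <- if (breadth_median == "tissue") median_exp
                 else apply(em$values, 1, median)
  breadth <- rowMeans(x > breadth_ref)
  zscore <- rowMeans(z[, smp, drop = FALSE])

  data.frame(gene = rownames(x), tissue = tissue,
             MeanExp = mean_exp, MedianExp = median_exp, SDofExp = sd_exp,
             CV = cv, MAD = madm, Breadth = breadth, ZScore = zscore,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression feature table over several tissues
#' @param em an [expression_matrix()].
#' @param tissue_set tissues to compute (default: all in `em`).
#' @param breadth_median passed to [tissue_expression_features()].
#' @return row-bound data.frame of per-tissue feature rows.
#' @export
expression_feature_table <- function(em, tissue_set = tissues(em),
                                     breadth_median = "tissue") {
  z <- pooled_zscore(em)
  do.call(rbind, lapply(tissue_set, function(t)
    tissue_expression_features(em, t, breadth_median, z = z)))
}
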