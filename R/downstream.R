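# Post-scoring analyses: top-fraction gene lists, SNP-to-gene trait maps,
# Fisher enrichment, linear-genome gene clustering with a chromosome-matched
# permutation null, TAD gene-coverage statistics, and TF-overlap tissue
# dendrograms with Newick export.

#' Top-scoring genes of one tissue
#'
#' The ceiling(frac * n) highest-scoring genes; ties across the cutoff are
#' broken by gene id, so the selection is deterministic.
#'
#' @param score_table score table.
#' @param tissue tissue label.
#' @param frac fraction in (0, 1].
#' @return character vector of gene ids.
#' @export
select_top_fraction <- function(score_table, tissue, frac) {
  if (!(frac > 0 && frac <= 1)) stop("frac must be in (0, 1]")
  sub <- score_table[score_table$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0) stop("tissue not scored: ", tissue)
  k <- ceiling(frac * nrow(sub))
  sub <- sub[order(-sub$score, sub$gene), , drop = FALSE]
  sub$gene[seq_len(k)]
}

#' Link traits to genes by intragenic genome-wide-significant SNPs
#'
#' A gene is linked to a trait iff it harbors a SNP with association
#' p-value < `p_max` whose position falls inside the gene's (0-based,
#' half-open) locus. Traits with fewer than `min_genes` linked genes are
#' dropped.
#'
#' @param snp_table data.frame with columns chrom, pos, p, trait.
#' @param ann a [gene_annotation()].
#' @param p_max association-p threshold (default 1e-10).
#' @param min_genes minimum genes per retained trait (default 5).
#' @return named list: trait -> character vector of gene ids.
#' @export
map_snps_to_genes <- function(snp_table, ann, p_max = 1e-10, min_genes = 5) {
  if (any(!is.finite(snp_table$pos)) || any(snp_table$pos < 0))
    stop("malformed SNP positions")
  hits <- snp_table[snp_table$p < p_max, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    in_gene <- ann$chrom == hits$chrom[i] &
      ann$start <= hits$pos[i] & hits$pos[i] < ann$end
    if (!any(in_gene)) next
    tr <- as.character(hits$trait[i])
    out[[tr]] <- union(out[[tr]], ann$gene_id[in_gene])
  }
  out[lengths(out) >= min_genes]
}

#' Fisher enrichment of a query gene set in a target set
#'
#' 2x2 table on the universe: a = |query & target|, b = |query \\ target|,
#' c = |target \\ query|, d = rest. Odds ratio is the sample OR
#' (a d)/(b c) (+Inf with `zero_cell = TRUE` when b or c is 0); the
#' p-value is the two-sided Fisher exact test.
#'
#' @param query,target,universe character gene-id vectors; query and target
#'   must be subsets of the universe.
#' @param OR_min,p_max pass thresholds (defaults 1.5 and 0.05).
#' @return list: a, b, c, d, odds_ratio, fisher_p, pass, zero_cell.
#' @export
set_enrichment <- function(query, target, universe, OR_min = 1.5,
                           p_max = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query); target <- unique(target)
  if (length(setdiff(query, universe)) || length(setdiff(target, universe)))
    stop("query and target must be subsets of the universe")
  a <- length(intersect(query, target))
  b <- length(query) - a
  c <- length(target) - a
  d <- length(universe) - a - b - c
  zero_cell <- (b == 0 || c == 0) && a > 0
  or <- if (b == 0 || c == 0) {
    if (a == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  p <- fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  list(a = a, b = b, c = c, d = d, odds_ratio = or, fisher_p = p,
       pass = isTRUE(or > OR_min && p < p_max), zero_cell = zero_cell)
}

#' Linear-genome clusters of a gene set
#'
#' Orders the members of `genes` along each chromosome by start coordinate
#' and segments them into maximal runs whose successive start coordinates
#' differ by at most `max_gap`. Runs with at least `min_genes` members are
#' clusters; `f` is the fraction of (annotated) members covered by
#' clusters.
#'
#' @param genes character gene ids.
#' @param ann a [gene_annotation()].
#' @param min_genes minimum run size to count as a cluster (default 5).
#' @param max_gap maximum successive start-to-start distance in bp
#'   (default 500000).
#' @return list: `clusters` (list of gene-id vectors), `f`,
#'   `n_genes_in_clusters`, `n_annotated`, `n_unannotated`.
#' @export
genomic_clusters <- function(genes, ann, min_genes = 5, max_gap = 5e5) {
  genes <- unique(genes)
  known <- genes[genes %in% ann$gene_id]
  n_un <- length(genes) - length(known)
  sub <- ann[ann$gene_id %in% known, , drop = FALSE]
  clusters <- list()
  for (ch in unique(sub$chrom)) {
    s <- sub[sub$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    run_id <- cumsum(c(1, diff(s$start) > max_gap))
    for (r in split(s$gene_id, run_id))
      if (length(r) >= min_genes) clusters[[length(clusters) + 1]] <- r
  }
  covered <- sum(lengths(clusters))
  list(clusters = clusters,
       f = if (length(known)) covered / length(known) else NA_real_,
       n_genes_in_clusters = covered,
       n_annotated = length(known), n_unannotated = n_un)
}

#' Chromosome-matched permutation null for a gene-set statistic
#'
#' Draws `n_resamples` random gene sets from the annotated universe with the
#' same size — and, when `chromosome_matched`, the same per-chromosome
#' composition — as the observed set, evaluates `statistic_fn` on each, and
#' reports the z-score and the add-one empirical p-value
#' `(1 + #{null at least as extreme}) / (1 + n)` in the requested tail.
#'
#' @param statistic_fn function(gene_ids) -> single number.
#' @param genes observed gene set (must be annotated).
#' @param ann a [gene_annotation()] defining the universe.
#' @param n_resamples default 1000.
#' @param seed RNG seed.
#' @param chromosome_matched match per-chromosome counts (default TRUE).
#' @param tail `"upper"` (clustering fraction) or `"lower"` (TAD counts).
#' @return list of class `ClusterStatResult`: observed, null_mean, null_sd,
#'   z, empirical_p, n_resamples, tail.
#' @export
permutation_null <- function(statistic_fn, genes, ann, n_resamples = 1000,
                             seed = 1L, chromosome_matched = TRUE,
                             tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  genes <- unique(genes)
  genes <- genes[genes %in% ann$gene_id]
  observed <- statistic_fn(genes)
  chrom_of <- setNames(ann$chrom, ann$gene_id)
  by_chrom <- split(ann$gene_id, ann$chrom)
  need <- table(chrom_of[genes])
  if (chromosome_matched) {
    avail <- vapply(names(need), function(ch) length(by_chrom[[ch]]), integer(1))
    if (any(need > avail))
      stop("more genes requested than available on chromosome(s): ",
           paste(names(need)[need > avail], collapse = ", "))
  }
  set.seed(seed)
  null <- vapply(seq_len(n_resamples), function(i) {
    draw <- if (chromosome_matched) {
      unlist(lapply(names(need), function(ch)
        sample(by_chrom[[ch]], need[[ch]])), use.names = FALSE)
    } else sample(ann$gene_id, length(genes))
    statistic_fn(draw)
  }, numeric(1))
  null_mean <- mean(null); null_sd <- sd(null)
  z <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  k <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
  p <- (1 + k) / (1 + n_resamples)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, empirical_p = p,
                 n_resamples = n_resamples, tail = tail),
            class = "ClusterStatResult")
}

#' @export
print.ClusterStatResult <- function(x, ...) {
  cat(sprintf("observed %.4g, null %.4g +/- %.4g, z = %.3f, p = %.4g (%s tail, %d resamples)\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$empirical_p,
              x$tail, x$n_resamples))
  invisible(x)
}

#' Number of TADs covering a gene set
#'
#' A gene belongs to the (unique, since TADs do not overlap) TAD containing
#' its start coordinate. Counts the distinct TADs holding at least
#' `min_genes_per_tad` members of `genes`; a smaller count for a fixed set
#' size indicates tighter packing into domains.
#'
#' @param genes character gene ids.
#' @param tads a [tad_set()].
#' @param ann a [gene_annotation()].
#' @param min_genes_per_tad default 2.
#' @return list: n_tads, n_uncovered (genes outside every TAD),
#'   `tad_members` (list keyed "chrom:start-end").
#' @export
tad_coverage <- function(genes, tads, ann, min_genes_per_tad = 2) {
  genes <- unique(genes)
  sub <- ann[ann$gene_id %in% genes, , drop = FALSE]
  tad_id <- rep(NA_character_, nrow(sub))
  for (i in seq_len(nrow(sub))) {
    hit <- tads$chrom == sub$chrom[i] &
      tads$start <= sub$start[i] & sub$start[i] < tads$end
    if (any(hit)) {
      j <- which(hit)[1]
      tad_id[i] <- sprintf("%s:%d-%d", tads$chrom[j], tads$start[j],
                           tads$end[j])
    }
  }
  members <- split(sub$gene_id, tad_id)
  full <- members[lengths(members) >= min_genes_per_tad]
  list(n_tads = length(full), n_uncovered = sum(is.na(tad_id)),
       tad_members = members)
}

#' Tissue dendrogram from top-k transcription-factor overlap
#'
#' Per tissue, takes the `top_k` highest-scoring transcription factors
#' (ties by gene id); the distance between two tissues is 1 minus the
#' Jaccard index of their TF sets. The distance matrix is clustered with
#' Ward linkage and the tree returned as an `hclust` plus its Newick
#' serialization.
#'
#' @param score_table score table covering the tissues.
#' @param tf_set character vector of transcription-factor gene ids.
#' @param top_k TFs per tissue (default 20); tissues with fewer scored TFs
#'   use all available (recorded in `short_tissues`).
#' @return list of class `TissueDistance`: `top_tfs` (per-tissue list),
#'   `dist` (symmetric matrix), `hclust`, `newick`, `short_tissues`.
#' @export
tissue_tf_dendrogram <- function(score_table, tf_set, top_k = 20) {
  ts <- sort(unique(score_table$tissue))
  if (length(ts) < 2) stop("need >= 2 tissues for a dendrogram")
  top <- lapply(ts, function(t) {
    sub <- score_table[score_table$tissue == t &
                         score_table$gene %in% tf_set, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$gene), , drop = FALSE]
    head(sub$gene, top_k)
  })
  names(top) <- ts
  short <- ts[lengths(top) < top_k]
  n <- length(ts)
  d <- matrix(0, n, n, dimnames = list(ts, ts))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- length(union(top[[i]], top[[j]]))
    jac <- if (u == 0) 0 else length(intersect(top[[i]], top[[j]])) / u
    d[i, j] <- d[j, i] <- 1 - jac
  }
  hc <- hclust(as.dist(d), method = "ward.D2")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(top_tfs = top, dist = d, hclust = hc, newick = nwk,
                 short_tissues = short),
            class = "TissueDistance")
}
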