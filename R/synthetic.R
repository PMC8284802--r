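# Synthetic study generator. Plants tissue-relevant genes with the effect
# directions seen in real data -- elevated tissue expression, lower
# within-tissue variability, network hubness, genomic co-location inside
# shared TADs -- so every pipeline stage can be exercised end-to-end with a
# known ground truth.

#' Configuration for a synthetic study
#'
#' Defaults describe a desk-scale study with strong planted effects:
#' log-normal baseline expression with gene- and tissue-level random
#' effects, positives shifted up by `z_shift` pooled log-SD units in their
#' tissue with sample noise scaled by `cv_ratio`, an Erdos-Renyi
#' interactome where positives receive `hub_boost` extra edges
#' (preferentially to TF/kinase nodes), and a subset of tissue-1 positives
#' laid out adjacently on chromosome 1 inside shared TADs.
#'
#' @param n_tissues,samples_per_tissue,n_genes study dimensions.
#' @param n_positive_per_tissue planted positives per tissue (disjoint
#'   across tissues).
#' @param n_negative_per_tissue labeled negatives per tissue (drawn from
#'   non-positives; ~10x positives gives the ~0.09 prevalence typical of
#'   curated gold sets).
#' @param z_shift mean log-expression shift of positives in their tissue,
#'   in pooled log-SD units (default 2).
#' @param cv_ratio multiplier (< 1) on positives' within-tissue noise SD
#'   (default 0.5).
#' @param hub_boost extra network edges per positive gene (default 10).
#' @param mean_degree background Erdos-Renyi mean degree (default 6).
#' @param fraction_tf,fraction_kinase gene class fractions.
#' @param n_clustered_positives tissue-1 positives placed adjacently on
#'   chromosome 1 (default 10).
#' @param cluster_span_bp genomic span of the planted cluster (default
#'   900 kb, i.e. successive starts 100 kb apart for 10 genes).
#' @param gene_spacing_bp spacing of non-clustered genes (default 1.2 Mb,
#'   comfortably beyond the 500 kb cluster gap).
#' @param n_chromosomes default 5.
#' @param tad_size_bp TAD tile width (default 1 Mb).
#' @param zero_quantile expression values below this pooled quantile are
#'   set to 0 (zero-inflation; default 0.05).
#' @param trait_size,trait_overlap size of the synthetic trait gene set and
#'   the fraction of it drawn from tissue-1 positives.
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 4, samples_per_tissue = 20, n_genes = 300,
                       n_positive_per_tissue = 15,
                       n_negative_per_tissue = 10 * n_positive_per_tissue,
                       z_shift = 2, cv_ratio = 0.5, hub_boost = 10,
                       mean_degree = 6,
                       fraction_tf = 0.10, fraction_kinase = 0.05,
                       n_clustered_positives = 10, cluster_span_bp = 9e5,
                       gene_spacing_bp = 1.2e6, n_chromosomes = 5,
                       tad_size_bp = 1e6, zero_quantile = 0.05,
                       trait_size = 20, trait_overlap = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tissues >= 2, cfg$samples_per_tissue >= 4,
            cfg$cv_ratio > 0, cfg$cv_ratio <= 1,
            cfg$n_positive_per_tissue * cfg$n_tissues < cfg$n_genes,
            is.finite(cfg$z_shift))
  if (cfg$n_clustered_positives > cfg$n_positive_per_tissue)
    stop("more clustered positives than positives per tissue")
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  if (cfg$n_clustered_positives > genes_per_chrom)
    stop("more clustered positives than genes that fit on a chromosome")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a complete synthetic study
#'
#' @param cfg a [sim_config()].
#' @return list with elements `expression` ([expression_matrix()]),
#'   `network` ([gene_network()]), `flags` (gene, is_tf, is_kinase),
#'   `annotation` ([gene_annotation()]), `tads` ([tad_set()]), `labels`
#'   (gene, tissue, label), `gold_tables` (disease_tissue, disease_gene,
#'   detection -- reproduce `labels` through [assemble_gold_set()]),
#'   `trait_sets` and `deg_sets` (GMT-shaped lists), and `truth`
#'   (positives per tissue, clustered genes).
#' @export
generate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  tissue_ids <- sprintf("T%d", seq_len(cfg$n_tissues))
  samples <- unlist(lapply(tissue_ids, function(t)
    sprintf("%s_S%02d", t, seq_len(cfg$samples_per_tissue))))
  sample_tissue <- setNames(rep(tissue_ids, each = cfg$samples_per_tissue),
                            samples)

  # planted positives: disjoint blocks; tissue 1's first genes carry the
  # genomic cluster, so keep them first in gene order
  pos_pool <- sample(genes)
  positives <- split(pos_pool[seq_len(cfg$n_positive_per_tissue * cfg$n_tissues)],
                     rep(tissue_ids, each = cfg$n_positive_per_tissue))
  positives <- positives[tissue_ids]
  clustered <- positives[[1]][seq_len(cfg$n_clustered_positives)]

  # --- expression -----------------------------------------------------------
  log_mu <- rnorm(cfg$n_genes, mean = log(50), sd = 1.0)
  names(log_mu) <- genes
  base_sd <- 0.5
  logx <- matrix(0, cfg$n_genes, length(samples),
                 dimnames = list(genes, samples))
  for (t in tissue_ids) {
    smp <- names(sample_tissue)[sample_tissue == t]
    t_eff <- rnorm(cfg$n_genes, 0, 0.3)
    mu_t <- log_mu + t_eff
    sd_t <- rep(base_sd, cfg$n_genes)
    is_pos <- genes %in% positives[[t]]
    # pooled log-SD is ~sqrt(0.3^2 + base_sd^2); shift in those units
    pooled_sd <- sqrt(0.3^2 + base_sd^2)
    mu_t[is_pos] <- mu_t[is_pos] + cfg$z_shift * pooled_sd
    sd_t[is_pos] <- sd_t[is_pos] * cfg$cv_ratio
    logx[, smp] <- mu_t + matrix(rnorm(cfg$n_genes * length(smp)),
                                 cfg$n_genes) * sd_t
  }
  x <- exp(logx)
  if (cfg$zero_quantile > 0) {
    thr <- quantile(x, cfg$zero_quantile)
    x[x < thr] <- 0
  }
  em <- expression_matrix(x, sample_tissue)

  # --- gene class flags -----------------------------------------------------
  n_tf <- round(cfg$fraction_tf * cfg$n_genes)
  n_kin <- round(cfg$fraction_kinase * cfg$n_genes)
  cls <- sample(genes, n_tf + n_kin)
  tf_genes <- cls[seq_len(n_tf)]
  kin_genes <- cls[n_tf + seq_len(n_kin)]
  flags <- data.frame(gene = genes,
                      is_tf = genes %in% tf_genes,
                      is_kinase = genes %in% kin_genes,
                      stringsAsFactors = FALSE)

  # --- network: ER background + hub boost for positives ---------------------
  p_edge <- cfg$mean_degree / (cfg$n_genes - 1)
  pairs <- which(upper.tri(matrix(0, cfg$n_genes, cfg$n_genes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(a = genes[pairs[keep, 1]], b = genes[pairs[keep, 2]],
                      stringsAsFactors = FALSE)
  all_pos <- unlist(positives, use.names = FALSE)
  w <- ifelse(genes %in% c(tf_genes, kin_genes), 3, 1)
  if (cfg$hub_boost > 0) {
    extra <- do.call(rbind, lapply(all_pos, function(g) {
      nb <- sample(setdiff(genes, g), cfg$hub_boost, prob = w[genes != g])
      data.frame(a = g, b = nb, stringsAsFactors = FALSE)
    }))
    edges <- rbind(edges, extra)
  }
  net <- gene_network(edges)

  # --- annotation: clustered genes tight on chr1, the rest spread out -------
  gene_order <- c(clustered, setdiff(genes, clustered))
  chrom <- paste0("chr", rep(seq_len(cfg$n_chromosomes),
                             each = ceiling(cfg$n_genes / cfg$n_chromosomes)))
  chrom <- chrom[seq_len(cfg$n_genes)]
  spacing_in <- if (cfg$n_clustered_positives > 1)
    cfg$cluster_span_bp / (cfg$n_clustered_positives - 1) else 0
  start <- numeric(cfg$n_genes)
  pos_cursor <- setNames(rep(0, cfg$n_chromosomes),
                         paste0("chr", seq_len(cfg$n_chromosomes)))
  for (i in seq_len(cfg$n_genes)) {
    ch <- chrom[i]
    start[i] <- pos_cursor[ch]
    step <- if (i < cfg$n_clustered_positives) spacing_in else cfg$gene_spacing_bp
    pos_cursor[ch] <- pos_cursor[ch] + step
  }
  ann <- gene_annotation(data.frame(
    gene_id = gene_order, chrom = chrom, start = start,
    end = start + 2e4, strand = ".", stringsAsFactors = FALSE))

  # --- TADs: tile every chromosome ------------------------------------------
  tads <- do.call(rbind, lapply(unique(ann$chrom), function(ch) {
    mx <- max(ann$end[ann$chrom == ch])
    brk <- seq(0, ceiling(mx / cfg$tad_size_bp) * cfg$tad_size_bp,
               by = cfg$tad_size_bp)
    data.frame(chrom = ch, start = head(brk, -1), end = tail(brk, -1))
  }))
  tads <- tad_set(tads)

  # --- labels + gold-set source tables --------------------------------------
  universe <- expand.grid(gene = genes, tissue = tissue_ids,
                          stringsAsFactors = FALSE)
  disease_tissue <- data.frame(disease = paste0("D_", tissue_ids),
                               tissue = tissue_ids, stringsAsFactors = FALSE)
  disease_gene <- do.call(rbind, lapply(tissue_ids, function(t)
    data.frame(disease = paste0("D_", t), gene = positives[[t]],
               stringsAsFactors = FALSE)))
  detection <- do.call(rbind, lapply(tissue_ids, function(t) {
    nonpos <- setdiff(genes, positives[[t]])
    neg <- sample(nonpos, min(cfg$n_negative_per_tissue, length(nonpos)))
    data.frame(gene = genes, tissue = t, detected = !(genes %in% neg),
               stringsAsFactors = FALSE)
  }))
  labels <- assemble_gold_set(disease_tissue, disease_gene, detection,
                              universe)

  # --- trait + DEG gene sets -------------------------------------------------
  n_hit <- round(cfg$trait_overlap * cfg$trait_size)
  trait <- c(sample(positives[[1]], min(n_hit, length(positives[[1]]))),
             sample(setdiff(genes, positives[[1]]), cfg$trait_size - n_hit))
  deg_up <- c(sample(positives[[1]], min(n_hit, length(positives[[1]]))),
              sample(setdiff(genes, positives[[1]]), cfg$trait_size - n_hit))
  deg_down <- sample(genes, cfg$trait_size)

  list(expression = em, network = net, flags = flags, annotation = ann,
       tads = tads, labels = labels,
       gold_tables = list(disease_tissue = disease_tissue,
                          disease_gene = disease_gene,
                          detection = detection),
       trait_sets = list(trait1 = trait),
       deg_sets = list(deg_up = unique(deg_up), deg_down = deg_down),
       truth = list(positives = positives, clustered = clustered),
       config = cfg)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' @param study output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Files: expression.tsv, tissue_map.tsv,
#'   edges.tsv, genes.bed, tads.bed, gene_classes.gmt, disease_tissue.tsv,
#'   disease_gene.tsv, detection.tsv, trait_sets.gmt, deg_sets.gmt.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  em <- study$expression
  expr <- data.frame(gene = rownames(em$values), em$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(expr, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(data.frame(sample = names(em$sample_tissue),
                                tissue = unname(em$sample_tissue)),
                     file.path(dir, "tissue_map.tsv"), sep = "\t")
  data.table::fwrite(network_edges(study$network),
                     file.path(dir, "edges.tsv"), sep = "\t",
                     col.names = FALSE)
  ann <- study$annotation
  data.table::fwrite(data.frame(ann$chrom, as.integer(ann$start),
                                as.integer(ann$end), ann$gene_id),
                     file.path(dir, "genes.bed"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(data.frame(study$tads$chrom,
                                as.integer(study$tads$start),
                                as.integer(study$tads$end)),
                     file.path(dir, "tads.bed"), sep = "\t",
                     col.names = FALSE)
  write_gmt(list(TF = study$flags$gene[study$flags$is_tf],
                 Kinase = study$flags$gene[study$flags$is_kinase]),
            file.path(dir, "gene_classes.gmt"))
  gt <- study$gold_tables
  data.table::fwrite(gt$disease_tissue, file.path(dir, "disease_tissue.tsv"),
                     sep = "\t")
  data.table::fwrite(gt$disease_gene, file.path(dir, "disease_gene.tsv"),
                     sep = "\t")
  data.table::fwrite(gt$detection, file.path(dir, "detection.tsv"),
                     sep = "\t")
  write_gmt(study$trait_sets, file.path(dir, "trait_sets.gmt"))
  write_gmt(study$deg_sets, file.path(dir, "deg_sets.gmt"))
  invisible(dir)
}
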