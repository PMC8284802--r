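# End-to-end orchestration: features -> labels -> model -> scores ->
# evaluation -> downstream statistics, from a single config, with a run
# manifest for reproducibility.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed root seed; every stage derives its own stream from it.
#' @param simulate when TRUE (default) the inputs come from
#'   [generate_study()] with `sim` as its config; otherwise the `paths`
#'   entries must name the input files.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param paths named list of input paths (expression, tissue_map, edges,
#'   genes_bed, tads_bed, gene_classes_gmt, disease_tissue, disease_gene,
#'   detection, trait_gmt, deg_gmt); used when `simulate = FALSE`.
#' @param params a [fugue_params()] (its seed is overridden by `seed`).
#' @param top_frac top-fraction defining nominal tissue-relevant genes
#'   (default 0.10).
#' @param cluster_top_frac fraction used for clustering/TAD/DEG analyses
#'   (default 0.05).
#' @param OR_min,p_max enrichment pass thresholds.
#' @param min_genes,max_gap genomic-cluster definition (5 genes, 500 kb).
#' @param min_genes_per_tad TAD membership threshold (default 2).
#' @param top_k_tf TFs per tissue for the dendrogram (default 20).
#' @param n_resamples permutation-null resamples (default 1000).
#' @param cv_repeats CV repeats the pipeline runs (default 10; the full 100
#'   is available via [fugue_params()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = "fugue_out", seed = 1L, simulate = TRUE,
                       sim = sim_config(), paths = list(),
                       params = fugue_params(), top_frac = 0.10,
                       cluster_top_frac = 0.05, OR_min = 1.5, p_max = 0.05,
                       min_genes = 5, max_gap = 5e5, min_genes_per_tad = 2,
                       top_k_tf = 20, n_resamples = 1000, cv_repeats = 10) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `sim` and `params`
#' sub-maps mirror [sim_config()] and [fugue_params()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  params <- do.call(fugue_params, y$params %||% list())
  y$sim <- NULL; y$params <- NULL
  do.call(run_config, c(y, list(sim = sim, params = params)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_inputs <- function(cfg) {
  if (isTRUE(cfg$simulate)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    return(generate_study(sim))
  }
  p <- cfg$paths
  need <- c("expression", "tissue_map", "edges", "genes_bed", "tads_bed",
            "gene_classes_gmt", "disease_tissue", "disease_gene", "detection")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("config is missing input path(s): ",
                         paste(miss, collapse = ", "))
  for (f in need) if (!file.exists(p[[f]]))
    stop("input file does not exist: ", p[[f]])
  em <- read_expression(p$expression, p$tissue_map)
  classes <- read_gmt(p$gene_classes_gmt)
  genes <- rownames(em$values)
  flags <- data.frame(gene = genes,
                      is_tf = genes %in% (classes$TF %||% character(0)),
                      is_kinase = genes %in% (classes$Kinase %||% character(0)),
                      stringsAsFactors = FALSE)
  list(expression = em,
       network = read_edge_list(p$edges),
       flags = flags,
       annotation = read_bed(p$genes_bed, "genes"),
       tads = read_bed(p$tads_bed, "tads"),
       gold_tables = list(
         disease_tissue = data.table::fread(p$disease_tissue, data.table = FALSE),
         disease_gene = data.table::fread(p$disease_gene, data.table = FALSE),
         detection = data.table::fread(p$detection, data.table = FALSE)),
       trait_sets = if (!is.null(p$trait_gmt)) read_gmt(p$trait_gmt) else list(),
       deg_sets = if (!is.null(p$deg_gmt)) read_gmt(p$deg_gmt) else list(),
       labels = NULL)
}

#' Run the full pipeline
#'
#' Stages: load/simulate inputs; compute the 14-feature table; assemble the
#' gold set; repeated CV; leave-one-group-out scoring of every pair;
#' evaluation (per-feature discrimination, rank tests); downstream
#' statistics (top-list enrichment against any provided trait/DEG sets,
#' genomic clustering and TAD coverage of the top list with permutation
#' nulls, TF-overlap dendrogram). All tables are written to
#' `cfg$out_dir` together with a `manifest.json`; re-running the same
#' config and seed reproduces the outputs byte for byte.
#'
#' @param cfg a [run_config()] or path to a YAML file.
#' @return (invisibly) a list with the in-memory results; side effect: the
#'   output directory.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  inputs <- stage("load_inputs", .load_inputs(cfg))
  em <- inputs$expression

  feats <- stage("features",
                 feature_table(em, inputs$network, inputs$flags))
  labels <- inputs$labels
  if (is.null(labels)) {
    gt <- inputs$gold_tables
    universe <- unique(feats[, c("gene", "tissue")])
    labels <- stage("labels",
                    assemble_gold_set(gt$disease_tissue, gt$disease_gene,
                                      gt$detection, universe))
  }
  feats <- merge(feats, labels, by = c("gene", "tissue"))
  params <- cfg$params
  params$seed <- cfg$seed

  cv <- stage("cv", repeated_cv(feats, params, n_repeats = cfg$cv_repeats))
  scores <- stage("score", loo_pair_scores(feats, params))
  disc <- stage("evaluate_features", feature_discrimination(feats))
  rks <- stage("evaluate_ranks", rank_tests(scores))
  zcmp <- stage("evaluate_zscore_baseline",
                compare_to_zscore_baseline(scores, feats))

  ts <- tissues(em)
  top5 <- lapply(ts, function(t)
    select_top_fraction(scores, t, cfg$cluster_top_frac))
  names(top5) <- ts
  clus <- stage("clusters", lapply(ts, function(t) {
    f_stat <- function(g) genomic_clusters(g, inputs$annotation,
                                           cfg$min_genes, cfg$max_gap)$f
    permutation_null(f_stat, top5[[t]], inputs$annotation,
                     n_resamples = cfg$n_resamples, seed = cfg$seed,
                     tail = "upper")
  }))
  names(clus) <- ts
  tadr <- stage("tads", lapply(ts, function(t) {
    t_stat <- function(g) tad_coverage(g, inputs$tads, inputs$annotation,
                                       cfg$min_genes_per_tad)$n_tads
    permutation_null(t_stat, top5[[t]], inputs$annotation,
                     n_resamples = cfg$n_resamples, seed = cfg$seed,
                     tail = "lower")
  }))
  names(tadr) <- ts

  enrich <- stage("enrich", {
    sets <- c(inputs$trait_sets, inputs$deg_sets)
    if (length(sets)) {
      do.call(rbind, lapply(ts, function(t) {
        uni <- scores$gene[scores$tissue == t]
        top10 <- select_top_fraction(scores, t, cfg$top_frac)
        do.call(rbind, lapply(names(sets), function(s) {
          tgt <- intersect(sets[[s]], uni)
          if (!length(tgt)) return(NULL)
          e <- set_enrichment(top10, tgt, uni, cfg$OR_min, cfg$p_max)
          data.frame(set = s, tissue = t, a = e$a, b = e$b, c = e$c, d = e$d,
                     odds_ratio = e$odds_ratio, fisher_p = e$fisher_p,
                     pass = e$pass)
        }))
      }))
    } else NULL
  })

  dend <- stage("dendrogram", {
    tf <- inputs$flags$gene[inputs$flags$is_tf]
    if (length(tf) && length(ts) >= 2)
      tissue_tf_dendrogram(scores, tf, top_k = cfg$top_k_tf) else NULL
  })

  # ---- write outputs --------------------------------------------------------
  od <- cfg$out_dir
  data.table::fwrite(feats, file.path(od, "feature_table.tsv"), sep = "\t")
  data.table::fwrite(labels, file.path(od, "labels.tsv"), sep = "\t")
  write_scores(scores, file.path(od, "scores.tsv"))
  data.table::fwrite(disc, file.path(od, "feature_discrimination.tsv"),
                     sep = "\t")
  data.table::fwrite(cv$per_repeat, file.path(od, "cv_metrics.tsv"),
                     sep = "\t")
  data.table::fwrite(rks$per_tissue, file.path(od, "rank_tests_tissue.tsv"),
                     sep = "\t")
  data.table::fwrite(zcmp, file.path(od, "zscore_baseline.tsv"), sep = "\t")
  if (!is.null(enrich))
    data.table::fwrite(enrich, file.path(od, "enrichment.tsv"), sep = "\t")
  cluster_tab <- data.frame(
    tissue = ts,
    f_observed = vapply(clus, function(x) x$observed, numeric(1)),
    f_z = vapply(clus, function(x) x$z, numeric(1)),
    f_p = vapply(clus, function(x) x$empirical_p, numeric(1)),
    ntad_observed = vapply(tadr, function(x) x$observed, numeric(1)),
    ntad_z = vapply(tadr, function(x) x$z, numeric(1)),
    ntad_p = vapply(tadr, function(x) x$empirical_p, numeric(1)))
  data.table::fwrite(cluster_tab, file.path(od, "cluster_stats.tsv"),
                     sep = "\t")
  if (!is.null(dend))
    writeLines(dend$newick, file.path(od, "tissue_dendrogram.nwk"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fugue")),
    seed = cfg$seed,
    params = unclass(params),
    thresholds = cfg[c("top_frac", "cluster_top_frac", "OR_min", "p_max",
                       "min_genes", "max_gap", "min_genes_per_tad",
                       "top_k_tf", "n_resamples", "cv_repeats")],
    cv = list(auROC_mean = cv$auROC_mean, auROC_sd = cv$auROC_sd,
              auPRC_mean = cv$auPRC_mean, auPRC_sd = cv$auPRC_sd))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(features = feats, labels = labels, scores = scores,
                 cv = cv, discrimination = disc, rank_tests = rks,
                 zscore_baseline = zcmp, enrichment = enrich,
                 cluster_stats = list(clusters = clus, tads = tadr),
                 dendrogram = dend, inputs = inputs, manifest = manifest))
}
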