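# Tissue projection of the global interactome and the seven network-derived
# features: degree, betweenness centrality (pair-normalized), local
# clustering coefficient, kinase/TF neighbor counts, and neighbor means of
# the expression z-score and breadth.

#' Project the global network into one tissue
#'
#' An edge {g1, g2} survives iff, in at least `min_frac` of the tissue's
#' samples, both genes are simultaneously expressed above their own pooled
#' median (median across all samples of all tissues). With
#' `rule = "marginal"` each gene's above-median fraction is tested
#' independently instead. Genes absent from the expression matrix are
#' dropped from the network (count kept in `dropped_genes`).
#'
#' @param em an [expression_matrix()].
#' @param net the global [gene_network()].
#' @param tissue tissue label.
#' @param min_frac minimum fraction of tissue samples (default 0.25).
#' @param rule `"joint"` (default) or `"marginal"` edge-retention rule.
#' @return A `GeneNetwork` for the tissue; nodes are all network genes
#'   measured in `em` (possibly isolated), edges the survivors.
#' @export
build_tissue_network <- function(em, net, tissue, min_frac = 0.25,
                                 rule = c("joint", "marginal")) {
  rule <- match.arg(rule)
  smp <- tissue_samples(em, tissue)
  nodes <- igraph::V(net$graph)$name
  keep_nodes <- nodes[nodes %in% rownames(em$values)]
  n_dropped <- length(nodes) - length(keep_nodes)

  med <- apply(em$values, 1, median)
  above <- em$values[, smp, drop = FALSE] > med  # genes x tissue samples

  el <- network_edges(net)
  el <- el[el$a %in% keep_nodes & el$b %in% keep_nodes, , drop = FALSE]
  if (nrow(el)) {
    frac <- if (rule == "joint") {
      rowMeans(above[el$a, , drop = FALSE] & above[el$b, , drop = FALSE])
    } else {
      pmin(rowMeans(above[el$a, , drop = FALSE]),
           rowMeans(above[el$b, , drop = FALSE]))
    }
    el <- el[frac >= min_frac, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = keep_nodes))
  structure(list(graph = g, tissue = tissue,
                 dropped_self_loops = 0L, dropped_duplicates = 0L,
                 dropped_genes = n_dropped),
            class = "GeneNetwork")
}

#' Topology features per node of a tissue network
#'
#' Degree; betweenness centrality with the standard pair normalization
#' (divided by the number of vertex pairs excluding the node, shortest-path
#' multiplicity weighted); local clustering coefficient
#' 2 * e(N(v)) / (deg (deg - 1)), defined as 0 when deg < 2.
#'
#' @param tn a tissue `GeneNetwork`.
#' @return data.frame with columns gene, Degree, Centrality_coeff,
#'   Clustering_coeff.
#' @export
topology_features <- function(tn) {
  g <- tn$graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = n > 2)
  if (n <= 2) btw[] <- 0
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  data.frame(gene = igraph::V(g)$name, Degree = as.integer(deg),
             Centrality_coeff = unname(btw), Clustering_coeff = cc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Neighbor-derived features per node
#'
#' Counts of kinase and transcription-factor neighbors, and neighbor means
#' of the expression ZScore and Breadth features (averaged over neighbors
#' with defined values). Isolated nodes get counts 0 and NA means.
#'
#' @param tn a tissue `GeneNetwork`.
#' @param flags data.frame with columns gene, is_tf, is_kinase; genes absent
#'   from it count as neither.
#' @param expr_rows expression feature rows ([tissue_expression_features()])
#'   for the same tissue.
#' @return data.frame with columns gene, NumOfKinaseNbs, NumOfTFNeighbors,
#'   NeighborMeanZscore, NeighborMeanBreadth.
#' @export
neighbor_features <- function(tn, flags, expr_rows) {
  if (!is.null(tn$tissue) && length(unique(expr_rows$tissue)) &&
      !identical(unique(expr_rows$tissue), tn$tissue))
    stop("expression rows are for tissue ", unique(expr_rows$tissue)[1],
         " but the network is for ", tn$tissue)
  g <- tn$graph
  genes <- igraph::V(g)$name
  is_kin <- setNames(rep(FALSE, length(genes)), genes)
  is_tf <- is_kin
  if (nrow(flags)) {
    hit <- intersect(flags$gene, genes)
    is_kin[hit] <- flags$is_kinase[match(hit, flags$gene)]
    is_tf[hit] <- flags$is_tf[match(hit, flags$gene)]
  }
  zs <- setNames(expr_rows$ZScore, expr_rows$gene)[genes]
  br <- setNames(expr_rows$Breadth, expr_rows$gene)[genes]

  adj <- igraph::as_adj_list(g, mode = "all")
  res <- lapply(seq_along(genes), function(i) {
    nb <- genes[as.integer(adj[[i]])]
    nb <- setdiff(nb, genes[i])
    if (!length(nb))
      return(c(kin = 0, tf = 0, z = NA_real_, b = NA_real_))
    c(kin = sum(is_kin[nb]), tf = sum(is_tf[nb]),
      z = mean(zs[nb], na.rm = TRUE), b = mean(br[nb], na.rm = TRUE))
  })
  m <- do.call(rbind, res)
  data.frame(gene = genes,
             NumOfKinaseNbs = as.integer(m[, "kin"]),
             NumOfTFNeighbors = as.integer(m[, "tf"]),
             NeighborMeanZscore = ifelse(is.nan(m[, "z"]), NA_real_, m[, "z"]),
             NeighborMeanBreadth = ifelse(is.nan(m[, "b"]), NA_real_, m[, "b"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Canonical order of the 14 feature columns
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  c("MeanExp", "SDofExp", "ZScore", "MedianExp", "Breadth", "CV", "MAD",
    "Centrality_coeff", "Clustering_coeff", "Degree",
    "NumOfKinaseNbs", "NumOfTFNeighbors",
    "NeighborMeanBreadth", "NeighborMeanZscore")
}

#' Full 14-column feature table over tissues
#'
#' Computes the 7 expression features and, per tissue, projects the network
#' and computes the 7 network features, merging on (gene, tissue). Genes
#' measured in expression but absent from the network get NA network
#' features (absence is signal, routed natively by the tree learner).
#'
#' @param em an [expression_matrix()].
#' @param net the global [gene_network()].
#' @param flags gene class flags data.frame (gene, is_tf, is_kinase).
#' @param tissue_set tissues (default all).
#' @param min_frac,rule passed to [build_tissue_network()].
#' @param breadth_median passed to [tissue_expression_features()].
#' @return data.frame: gene, tissue, then the 14 [feature_names()] columns.
#' @export
feature_table <- function(em, net, flags, tissue_set = tissues(em),
                          min_frac = 0.25, rule = "joint",
                          breadth_median = "tissue") {
  z <- pooled_zscore(em)
  out <- lapply(tissue_set, function(t) {
    ex <- tissue_expression_features(em, t, breadth_median, z = z)
    tn <- build_tissue_network(em, net, t, min_frac = min_frac, rule = rule)
    topo <- topology_features(tn)
    nbr <- neighbor_features(tn, flags, ex)
    netf <- merge(topo, nbr, by = "gene")
    merged <- merge(ex, netf, by = "gene", all.x = TRUE)
    merged
  })
  res <- do.call(rbind, out)
  res[, c("gene", "tissue", feature_names())]
}
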