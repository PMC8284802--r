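#' @import data.table
#' @importFrom stats median sd quantile rbinom rnorm runif rlnorm wilcox.test
#'   fisher.test ks.test phyper setNames complete.cases p.adjust as.dist hclust
#' @importFrom utils head tail
NULL

# ---- expression matrix ------------------------------------------------------

#' Construct a validated expression matrix
#'
#' Bundles a genes x samples matrix of nonnegative normalized expression
#' (e.g. TPM) with a sample -> tissue assignment. All downstream expression
#' and network-projection steps consume this container.
#'
#' @param values numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required); finite, nonnegative.
#' @param sample_tissue named character vector mapping every sample id
#'   (names) to a tissue label.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `sample_tissue`.
#' @export
expression_matrix <- function(values, sample_tissue) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be nonnegative")
  missing_samples <- setdiff(colnames(values), names(sample_tissue))
  if (length(missing_samples))
    stop("samples missing from the tissue map: ",
         paste(missing_samples, collapse = ", "))
  sample_tissue <- sample_tissue[colnames(values)]
  tab <- table(sample_tissue)
  if (any(tab < 2))
    stop("every tissue needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(values = values, sample_tissue = sample_tissue),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_tissue))))
  invisible(x)
}

#' Tissues of an expression matrix
#' @param em an `ExpressionMatrix`.
#' @return character vector of tissue labels (sorted, unique).
#' @export
tissues <- function(em) sort(unique(unname(em$sample_tissue)))

#' Sample ids belonging to one tissue
#' @param em an `ExpressionMatrix`.
#' @param tissue tissue label.
#' @return character vector of sample ids.
#' @export
tissue_samples <- function(em, tissue) {
  if (!tissue %in% em$sample_tissue)
    stop("unknown tissue: ", tissue)
  names(em$sample_tissue)[em$sample_tissue == tissue]
}

#' Read an expression matrix with its sample -> tissue map
#'
#' Accepts either plain TSV (first column = gene id, header = sample ids) or
#' GCT 1.2. The tissue map is a two-column TSV (sample, tissue) with header.
#' Samples present in the matrix but absent from the map are an error;
#' extra map rows are ignored.
#'
#' @param matrix_path path to the expression TSV or GCT file.
#' @param tissue_map_path path to the sample -> tissue TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, tissue_map_path) {
  first <- readLines(matrix_path, n = 1L)
  if (identical(substr(first, 1, 4), "#1.2")) {
    vals <- .read_gct(matrix_path)
  } else {
    dt <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    gene_ids <- as.character(dt[[1]])
    body <- dt[, -1, drop = FALSE]
    if (!all(vapply(body, is.numeric, logical(1))))
      stop("non-numeric expression values in ", matrix_path)
    vals <- as.matrix(body)
    rownames(vals) <- gene_ids
  }
  map <- data.table::fread(tissue_map_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (ncol(map) < 2) stop("tissue map must have two columns (sample, tissue)")
  st <- setNames(as.character(map[[2]]), as.character(map[[1]]))
  expression_matrix(vals, st)
}

.read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GCT file: ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  dt <- data.table::fread(text = lines[-(1:2)], sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) != dims[1] || ncol(dt) - 2L != dims[2])
    stop(sprintf("GCT dimension line (%d x %d) disagrees with body (%d x %d)",
                 dims[1], dims[2], nrow(dt), ncol(dt) - 2L))
  vals <- as.matrix(dt[, -(1:2), drop = FALSE])
  rownames(vals) <- as.character(dt[[1]])
  vals
}

# ---- networks ---------------------------------------------------------------

#' Construct an undirected simple gene network
#'
#' @param edges two-column character matrix or data.frame of gene-id pairs.
#' @param tissue optional tissue label for a tissue-projected network.
#' @return Object of class `GeneNetwork`: list with `graph` (an
#'   [igraph::graph]), `tissue`, and counts of dropped self-loops/duplicates.
#' @export
gene_network <- function(edges, tissue = NULL) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("a", "b")
  edges$a <- as.character(edges$a); edges$b <- as.character(edges$b)
  nodes <- unique(c(edges$a, edges$b))  # a self-loop still names a node
  self <- edges$a == edges$b
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, tissue = tissue,
                 dropped_self_loops = n_self, dropped_duplicates = n_dup),
            class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork%s: %d nodes, %d edges\n",
              if (is.null(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Read a global interaction network from a two-column edge list
#'
#' Extra columns (e.g. confidence scores) are ignored. Self-loops and
#' duplicate edges (in either orientation) are dropped, with counts kept on
#' the returned object.
#'
#' @param path TSV edge list of gene symbols; no header expected, but a
#'   header row whose first field is non-gene-like is tolerated.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty edge list: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (nrow(dt) == 0) stop("empty edge list: ", path)
  if (ncol(dt) < 2) stop("edge list needs two columns: ", path)
  gene_network(dt[, 1:2])
}

#' Edge set of a network as a sorted two-column data.frame
#' @param net a `GeneNetwork`.
#' @return data.frame with columns `a`, `b` (a < b lexicographically).
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  if (nrow(el) == 0)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(a = pmin(el[, 1], el[, 2]), b = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- BED intervals ----------------------------------------------------------

#' Read gene annotation or TAD intervals from BED
#'
#' Coordinates are BED-native: 0-based, half-open. For `type = "genes"` the
#' 4th column (name) is required and must be unique; for `type = "tads"`
#' overlapping intervals on the same chromosome are rejected.
#'
#' @param path BED3/BED4 file.
#' @param type `"genes"` or `"tads"`.
#' @return data.frame with columns `chrom`, `start`, `end` (+ `gene_id`,
#'   `strand` for genes), sorted by chromosome then start; class
#'   `GeneAnnotation` or `TadSet` prepended.
#' @export
read_bed <- function(path, type = c("genes", "tads")) {
  type <- match.arg(type)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (nrow(dt) == 0) stop("empty BED file: ", path)
  names(dt)[1:3] <- c("chrom", "start", "end")
  dt$chrom <- as.character(dt$chrom)
  dt$start <- as.numeric(dt$start); dt$end <- as.numeric(dt$end)
  if (type == "genes") {
    if (ncol(dt) < 4) stop("gene annotation BED needs a 4th (name) column")
    ann <- data.frame(gene_id = as.character(dt[[4]]),
                      chrom = dt$chrom, start = dt$start, end = dt$end,
                      strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
                      stringsAsFactors = FALSE)
    gene_annotation(ann)
  } else {
    tad_set(dt[, c("chrom", "start", "end")])
  }
}

#' Validate a gene annotation table
#' @param ann data.frame with columns gene_id, chrom, start, end
#'   (0-based half-open) and optionally strand.
#' @return the validated data.frame, class `GeneAnnotation`, sorted.
#' @export
gene_annotation <- function(ann) {
  ann <- as.data.frame(ann)
  if (is.null(ann$strand)) ann$strand <- "."
  if (any(ann$start >= ann$end))
    stop("interval with start >= end for gene(s): ",
         paste(head(ann$gene_id[ann$start >= ann$end], 5), collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  if (!all(ann$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}

#' Validate a set of TAD intervals
#'
#' Intervals are 0-based half-open; abutting is allowed, overlap within a
#' chromosome is an error (a gene must map to at most one TAD).
#'
#' @param intervals data.frame with columns chrom, start, end.
#' @return validated data.frame, class `TadSet`, sorted.
#' @export
tad_set <- function(intervals) {
  iv <- as.data.frame(intervals)[, c("chrom", "start", "end")]
  if (any(iv$start >= iv$end)) stop("TAD interval with start >= end")
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping TAD intervals on ", ch)
  }
  rownames(iv) <- NULL
  class(iv) <- c("TadSet", "data.frame")
  iv
}

# ---- GMT gene sets ----------------------------------------------------------

#' Read named gene sets from a GMT file
#'
#' Standard GMT: tab-separated `name  description  member1  member2 ...`.
#' Members are de-duplicated per set; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields")
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  sets
}

#' Write named gene sets to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = ".") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# ---- score tables -----------------------------------------------------------

#' Write a score table to TSV
#'
#' Columns `gene`, `tissue`, `label`, `score`, `normalized_rank`, ordered by
#' tissue, then descending score, then gene id (deterministic, stable under
#' ties).
#'
#' @param score_table data.frame with those columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(score_table, path) {
  need <- c("gene", "tissue", "label", "score", "normalized_rank")
  miss <- setdiff(need, names(score_table))
  if (length(miss)) stop("score table missing column(s): ",
                         paste(miss, collapse = ", "))
  st <- as.data.frame(score_table)[, need]
  st <- st[order(st$tissue, -st$score, st$gene), , drop = FALSE]
  data.table::fwrite(st, path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}

#' Read back a score table written by [write_scores()]
#' @param path TSV path.
#' @return data.frame with the five score-table columns.
#' @export
read_scores <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    colClasses = list(character = c("gene", "tissue", "label")))
}
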