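# Gold-set assembly: positives from disease->tissue x disease->gene joins,
# negatives from absence of protein detection, everything else unlabeled.

#' Assemble Positive / Negative / Unlabeled gene-tissue labels
#'
#' A pair (g, t) is **P** iff some disease d maps to tissue t and to gene g.
#' Remaining pairs default to **U**; a U pair becomes **N** iff the protein
#' detection table says the gene's protein is not detected in that tissue.
#' Pairs absent from the detection table stay U. P takes precedence over N
#' (a disease-linked but undetected pair is P); such conflicts are counted
#' in the `conflicts` attribute.
#'
#' @param disease_tissue data.frame with columns `disease`, `tissue`.
#' @param disease_gene data.frame with columns `disease`, `gene`.
#' @param detection data.frame with columns `gene`, `tissue`, `detected`
#'   (logical).
#' @param universe data.frame with columns `gene`, `tissue`: all pairs to
#'   label.
#' @return data.frame (gene, tissue, label in {"P","N","U"}) covering the
#'   universe exactly, with attribute `conflicts` (count of P-over-N
#'   precedence events).
#' @export
assemble_gold_set <- function(disease_tissue, disease_gene, detection,
                              universe) {
  if (nrow(universe) == 0) stop("empty (gene, tissue) universe")
  uni_t <- unique(universe$tissue)
  bad_t <- setdiff(unique(disease_tissue$tissue), uni_t)
  if (length(bad_t))
    stop("disease-tissue map names unknown tissue(s): ",
         paste(bad_t, collapse = ", "))

  pos <- merge(disease_tissue, disease_gene, by = "disease")
  pos_key <- unique(paste(pos$gene, pos$tissue, sep = "\r"))
  uni_key <- paste(universe$gene, universe$tissue, sep = "\r")
  if (anyDuplicated(uni_key)) stop("duplicate (gene, tissue) pairs in universe")

  label <- rep("U", nrow(universe))
  is_p <- uni_key %in% pos_key
  label[is_p] <- "P"

  det <- detection[!is.na(detection$detected) & !detection$detected, ,
                   drop = FALSE]
  neg_key <- paste(det$gene, det$tissue, sep = "\r")
  is_n <- uni_key %in% neg_key
  conflicts <- sum(is_p & is_n)
  label[is_n & !is_p] <- "N"

  out <- data.frame(gene = universe$gene, tissue = universe$tissue,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "conflicts") <- conflicts
  out
}

#' Label counts and prevalence of a labeled-pair table
#' @param labels data.frame with a `label` column in {"P","N","U"}.
#' @return list with n_positive, n_negative, n_unlabeled, n_total and
#'   `prevalence` = P / (P + N), the random-classifier auPRC expectation.
#' @export
gold_set_summary <- function(labels) {
  n_p <- sum(labels$label == "P")
  n_n <- sum(labels$label == "N")
  n_u <- sum(labels$label == "U")
  list(n_positive = n_p, n_negative = n_n, n_unlabeled = n_u,
       n_total = nrow(labels),
       prevalence = if (n_p + n_n > 0) n_p / (n_p + n_n) else NA_real_)
}
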