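# Small in-code fixtures shared across test files.

# 3 genes x 4 samples, two tissues of two samples each
tiny_em <- function() {
  v <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                0, 0, 2, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  expression_matrix(v, c(s1 = "T1", s2 = "T1", s3 = "T2", s4 = "T2"))
}

# one gene with values 1..6 over three tissues of two samples
em_1to6 <- function() {
  v <- matrix(1:6, nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  expression_matrix(v, setNames(rep(c("TA", "TB", "TC"), each = 2),
                                paste0("s", 1:6)))
}

# labeled feature table with one planted informative feature; every other
# feature is label-independent noise
planted_feature_table <- function(n_pos = 60, n_neg = 600, seed = 1,
                                  informative = "ZScore", shift = 3) {
  set.seed(seed)
  n <- n_pos + n_neg
  ft <- data.frame(gene = sprintf("g%04d", seq_len(n)), tissue = "T1",
                   label = rep(c("P", "N"), c(n_pos, n_neg)),
                   stringsAsFactors = FALSE)
  for (f in feature_names()) ft[[f]] <- rnorm(n)
  ft[[informative]] <- ft[[informative]] + shift * (ft$label == "P")
  ft
}

# annotation with irregular but dense spacing, so cluster fractions of
# random gene sets vary smoothly (used for null-calibration checks)
calibration_annotation <- function(n_genes = 200, n_chrom = 4, seed = 5) {
  set.seed(seed)
  per <- n_genes / n_chrom
  starts <- as.numeric(unlist(lapply(seq_len(n_chrom), function(i)
    cumsum(sample(seq(5e4, 3e5, 5e4), per, TRUE)))))
  gene_annotation(data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = paste0("chr", rep(seq_len(n_chrom), each = per)),
    start = starts, end = starts + 2e4, stringsAsFactors = FALSE))
}
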