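# Independent brute-force oracles used to cross-check the implementation.
# They share no code path with the package internals (matrix powers instead
# of graph libraries, explicit pair counting instead of rank identities).

# pair-normalized betweenness via shortest-path counting with matrix powers
brute_betweenness <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- 1
    A[edges$b[i], edges$a[i]] <- 1
  }
  # dist and path counts from powers of A
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- diag(n)  # number of shortest paths
  P <- diag(n)  # A^L
  for (L in seq_len(n)) {
    P <- P %*% A
    newly <- is.infinite(D) & P > 0
    D[newly] <- L
    S[newly] <- P[newly]
  }
  btw <- setNames(numeric(n), nodes)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        tot <- tot + S[s, v] * S[v, t] / S[s, t]
    }
    btw[v] <- tot
  }
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

# local clustering coefficient straight from the adjacency matrix
brute_clustering <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- 1
    A[edges$b[i], edges$a[i]] <- 1
  }
  vapply(nodes, function(v) {
    nb <- nodes[A[v, ] == 1]
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

# auROC by explicit positive-negative pair counting (ties count 1/2)
brute_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# two-sided Fisher p by hypergeometric enumeration over one margin
brute_fisher_p <- function(a, b, c, d) {
  m <- a + b        # query size
  k <- a + c        # target size
  n_tot <- a + b + c + d
  lo <- max(0, k - (n_tot - m)); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_tot - m, k)
  obs <- dhyper(a, m, n_tot - m, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# fraction of genes covered by >= min_genes runs, by explicit scan
brute_cluster_fraction <- function(genes, ann, min_genes, max_gap) {
  sub <- ann[ann$gene_id %in% genes, , drop = FALSE]
  covered <- 0
  for (ch in unique(sub$chrom)) {
    s <- sort(sub$start[sub$chrom == ch])
    run_len <- 1
    for (i in seq_along(s)) {
      if (i > 1 && s[i] - s[i - 1] <= max_gap) {
        run_len <- run_len + 1
      } else {
        if (i > 1 && run_len >= min_genes) covered <- covered + run_len
        run_len <- 1
      }
    }
    if (run_len >= min_genes) covered <- covered + run_len
  }
  covered / nrow(sub)
}

# random simple undirected graph as an edge data.frame
random_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# gene sets realizing a given 2x2 table on a letter universe
sets_from_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  uni <- sprintf("u%03d", seq_len(n))
  list(query = uni[seq_len(a + b)],
       target = c(uni[seq_len(a)], uni[a + b + seq_len(c)]),
       universe = uni)
}
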