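# Independent oracles used across tests. These deliberately avoid the
# package's own counting/summation code paths.

# Brute-force graphlet orbit counts: enumerate every 3- and 4-node subset,
# keep connected induced subgraphs, classify by internal degree sequence.
brute_force_orbits <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0L, n, n)
  if (n_edges(net) > 0L) {
    i <- match(net$edges[, 1L], nodes)
    j <- match(net$edges[, 2L], nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  counts <- matrix(0L, n, 15L)
  counts[, 1L] <- rowSums(A)
  for (k in 3:4) {
    if (n < k) next
    for (cmb in asplit(utils::combn(n, k), 2L)) {
      sub <- A[cmb, cmb]
      g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
      if (!igraph::is_connected(g)) next
      deg <- rowSums(sub)
      e <- sum(sub) / 2
      orb <-
        if (k == 3) {
          if (e == 2) ifelse(deg == 1, 1, 2) else rep(3, 3)
        } else if (e == 3) {
          if (max(deg) == 3) ifelse(deg == 3, 7, 6) else ifelse(deg == 1, 4, 5)
        } else if (e == 4) {
          if (max(deg) == 2) rep(8, 4) else c(9, 10, 11)[match(deg, 1:3)]
        } else if (e == 5) {
          ifelse(deg == 2, 12, 13)
        } else {
          rep(14, 4)
        }
      for (t in seq_along(cmb)) {
        counts[cmb[t], orb[t] + 1L] <- counts[cmb[t], orb[t] + 1L] + 1L
      }
    }
  }
  colnames(counts) <- paste0("orbit", 0:14)
  rownames(counts) <- nodes
  counts
}

# Random test network from an edge probability, as a gene_network.
random_test_network <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("n%02d", seq_len(n))
  if (nrow(el) == 0L) return(gene_network(nodes))
  gene_network(nodes, cbind(nodes[el[, 1L]], nodes[el[, 2L]]))
}

# Exact hypergeometric upper-tail by direct combinatorial summation.
brute_force_enrichment_p <- function(X, N, K, M) {
  i <- X:min(N, K)
  sum(choose(K, i) * choose(M - K, N - i)) / choose(M, N)
}

brute_force_depletion_p <- function(X, N, K, M) {
  i <- 0:X
  sum(choose(K, i) * choose(M - K, N - i)) / choose(M, N)
}

# Adjusted Rand index between two labelings (via mclust when available).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
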