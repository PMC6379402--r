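#' Hypergeometric enrichment and depletion probabilities
#'
#' Sampling-without-replacement tail probabilities for a set of `N` genes
#' drawn from a background of `M` genes of which `K` carry the annotation,
#' `X` of them inside the set. The enrichment p-value is
#' `P(X' >= X) = 1 - sum_{i=0}^{X-1} C(K,i) C(M-K,N-i) / C(M,N)` and the
#' depletion p-value is `P(X' <= X)`. Computed in log space via the
#' hypergeometric distribution, so large backgrounds do not overflow.
#'
#' @param X Annotated genes inside the set.
#' @param N Set size (annotated genes only).
#' @param K Annotated genes in the background.
#' @param M Background size (annotated genes only).
#' @return A probability in `(0, 1]`.
#' @examples
#' hypergeom_enrichment_p(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_enrichment_p <- function(X, N, K, M) {
  check_hyper_bounds(X, N, K, M)
  stats::phyper(X - 1, K, M - K, N, lower.tail = FALSE)
}

#' @rdname hypergeom_enrichment_p
#' @export
depletion_p <- function(X, N, K, M) {
  check_hyper_bounds(X, N, K, M)
  stats::phyper(X, K, M - K, N, lower.tail = TRUE)
}

check_hyper_bounds <- function(X, N, K, M) {
  if (any(X < 0) || any(X > pmin(N, K)) || any(N > M) || any(K > M) ||
      any(N < 0) || any(K < 0)) {
    stop("hypergeometric bounds violated: need 0 <= X <= min(N, K), N <= M, K <= M")
  }
  invisible(TRUE)
}

#' Fold enrichment
#'
#' `(X/N) / (K/M)`: the frequency of annotated genes in the set relative to
#' the background. Values above 1 route to the enrichment tail, values at or
#' below 1 to the depletion tail.
#'
#' @inheritParams hypergeom_enrichment_p
#' @return Non-negative ratio.
#' @export
fold_enrichment <- function(X, N, K, M) {
  if (any(N == 0) || any(K == 0)) stop("fold enrichment undefined for N = 0 or K = 0")
  check_hyper_bounds(X, N, K, M)
  (X / N) / (K / M)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction, order-preserving and monotone;
#' a thin wrapper over [stats::p.adjust()] with input validation.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Cluster-level annotation enrichment and clustering quality
#'
#' For every (cluster, term) pair, tests whether the term is over-represented
#' in the cluster with the hypergeometric enrichment tail. Only annotated
#' genes count: `N` is the number of annotated genes in the cluster and `M`
#' the number of annotated genes overall. BH correction is applied jointly
#' across all (cluster, term) pairs; a term is enriched in a cluster when its
#' adjusted p-value is at most `alpha`. The clustering-quality summary
#' `percent_covered` is the percentage of annotated genes having at least
#' one of their own annotations enriched in their own cluster.
#'
#' @param clustering Named integer vector gene -> cluster.
#' @param annotations Named list term -> gene identifiers (e.g. [read_gmt()]).
#' @param alpha Significance threshold on adjusted p-values (default 0.05).
#' @return List with `table` (tibble: cluster, term, X, N, K, M, fold,
#'   p_raw, p_adjusted, enriched) and `percent_covered` in `[0, 100]`.
#' @export
cluster_enrichment <- function(clustering, annotations, alpha = 0.05) {
  genes <- names(clustering)
  annotations <- lapply(annotations, intersect, x = genes)
  annotations <- annotations[vapply(annotations, length, 1L) > 0L]
  annotated <- unique(unlist(annotations, use.names = FALSE))
  if (length(annotated) == 0L) stop("no annotated genes in the clustering universe")
  M <- length(annotated)
  rows <- list()
  for (cl in sort(unique(clustering))) {
    members <- intersect(genes[clustering == cl], annotated)
    N <- length(members)
    if (N == 0L) next
    for (term in names(annotations)) {
      ann <- annotations[[term]]
      K <- length(ann)
      X <- length(intersect(members, ann))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cluster = cl, term = term, X = X, N = N, K = K, M = M,
        fold = fold_enrichment(X, N, K, M),
        p_raw = hypergeom_enrichment_p(X, N, K, M)
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab$p_adjusted <- bh_adjust(tab$p_raw)
  tab$enriched <- tab$p_adjusted <= alpha
  enriched_terms <- split(tab$term[tab$enriched], tab$cluster[tab$enriched])
  covered <- vapply(annotated, function(g) {
    own_terms <- names(annotations)[vapply(annotations, function(a) g %in% a, TRUE)]
    cl <- as.character(clustering[[g]])
    any(own_terms %in% enriched_terms[[cl]])
  }, TRUE)
  list(table = tab, percent_covered = 100 * mean(covered))
}

#' Marker enrichment statistics for one gene set
#'
#' Counts marker genes inside a gene set against a named background, routes
#' to the enrichment tail when the fold enrichment exceeds 1 and to the
#' depletion tail otherwise.
#'
#' @param set Character vector of genes (must be a subset of `background`).
#' @param background Character vector: the background gene universe.
#' @param markers Character vector of marker genes (e.g. known cancer
#'   drivers); only markers inside the background count.
#' @return One-row tibble: X, N, K, M, fold, p, direction.
#' @export
gene_set_stats <- function(set, background, markers) {
  set <- unique(set); background <- unique(background); markers <- unique(markers)
  if (!all(set %in% background)) stop("gene set is not a subset of the background")
  K <- length(intersect(markers, background))
  if (K == 0L) stop("no marker genes in the background (K = 0)")
  N <- length(set)
  if (N == 0L) stop("empty gene set")
  M <- length(background)
  X <- length(intersect(set, markers))
  fold <- fold_enrichment(X, N, K, M)
  if (fold > 1) {
    tibble::tibble(X = X, N = N, K = K, M = M, fold = fold,
                   p = hypergeom_enrichment_p(X, N, K, M), direction = "enriched")
  } else {
    tibble::tibble(X = X, N = N, K = K, M = M, fold = fold,
                   p = depletion_p(X, N, K, M), direction = "depleted")
  }
}

#' Empirical permutation p-value
#'
#' `(r + 1) / (n + 1)` for `r` of `n` randomized replicates matching or
#' exceeding the observed statistic — the add-one empirical tail probability
#' of a permutation test.
#'
#' @param r Number of replicates at or above the observed value.
#' @param n Number of replicates.
#' @return Probability in `(0, 1]`.
#' @export
empirical_permutation_p <- function(r, n) {
  stopifnot(n >= 1)
  if (any(r < 0) || any(r > n)) stop("need 0 <= r <= n")
  (r + 1) / (n + 1)
}
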