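#' Simulate a multiplex network with planted co-clusters
#'
#' Generates `m` layers over one shared set of `n` genes partitioned into `k`
#' planted clusters (round-robin, so sizes differ by at most one). Within
#' each layer, a within-cluster gene pair carries an edge with probability
#' `p_in` and a between-cluster pair with probability `p_out` — a multi-layer
#' stochastic block model with assortative structure shared across layers,
#' emulating condition-specific molecular layers that reflect one underlying
#' functional organization.
#'
#' @param n Number of genes.
#' @param k Number of planted clusters (n divisible by k recommended).
#' @param m Number of layers.
#' @param p_in,p_out Edge probabilities within / between clusters; requires
#'   `p_out <= p_in`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `planted_multiplex`: list with `multiplex`
#'   (`multiplex_networks`), `truth` (named integer vector gene -> cluster),
#'   and `params`.
#' @examples
#' pm <- simulate_multiplex(n = 60, k = 3, m = 2, p_in = 0.4, p_out = 0.05, seed = 7)
#' table(pm$truth)
#' @export
simulate_multiplex <- function(n, k, m, p_in, p_out, seed) {
  stopifnot(n >= k, k >= 1, m >= 1,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  if (p_in < p_out) stop("p_in < p_out: degenerate planted structure")
  set.seed(seed)
  genes <- sprintf("g%0*d", nchar(n), seq_len(n))
  truth <- rep(seq_len(k), length.out = n)
  names(truth) <- genes
  same <- outer(truth, truth, `==`)
  up <- upper.tri(same)
  p_pair <- ifelse(same[up], p_in, p_out)
  mats <- lapply(seq_len(m), function(i) {
    A <- matrix(0, n, n, dimnames = list(genes, genes))
    A[up][stats::runif(length(p_pair)) < p_pair] <- 1
    A + t(A)
  })
  names(mats) <- paste0("layer", seq_len(m))
  structure(
    list(
      multiplex = multiplex_networks(genes, mats),
      truth = truth,
      params = list(n = n, k = k, m = m, p_in = p_in, p_out = p_out, seed = seed)
    ),
    class = "planted_multiplex"
  )
}

#' @export
print.planted_multiplex <- function(x, ...) {
  p <- x$params
  cat(sprintf("<planted_multiplex> n = %d, k = %d, m = %d, p_in = %g, p_out = %g, seed = %d\n",
              p$n, p$k, p$m, p$p_in, p$p_out, p$seed))
  invisible(x)
}

#' Simulate a control/case condition pair with planted rewired genes
#'
#' The case condition copies the control multiplex, then rewires a chosen set
#' of genes: per gene and per layer, a fraction `rewiring_strength` of its
#' incident edges is removed and replaced by the same number of edges to
#' uniformly chosen non-neighbors. Degree is preserved approximately (the
#' replacement count equals the removal count). All genes are marked
#' expressed in both conditions unless a silencing fraction is given, in
#' which case that fraction of non-rewired genes is silenced in the case
#' condition — so the planted rewired genes are always in the
#' always-expressed pool.
#'
#' @param base A `planted_multiplex` (the control condition).
#' @param n_rewired Number of genes to rewire.
#' @param rewiring_strength Fraction in `[0, 1]` of each gene's incident
#'   edges (per layer) that are moved.
#' @param seed Integer seed.
#' @param silenced_fraction Fraction of non-rewired genes silenced in the
#'   case condition (default 0).
#' @return A `condition_pair`: list with `control` and `case`
#'   (`multiplex_networks`), `rewired_genes`, and `expression` (named list
#'   `control` / `case` of expressed-gene sets).
#' @export
simulate_condition_pair <- function(base, n_rewired, rewiring_strength, seed,
                                    silenced_fraction = 0) {
  stopifnot(inherits(base, "planted_multiplex"))
  if (rewiring_strength < 0 || rewiring_strength > 1) {
    stop("rewiring_strength must be in [0, 1]")
  }
  genes <- base$multiplex$gene_index
  n <- length(genes)
  stopifnot(n_rewired <= n)
  set.seed(seed)
  rewired <- sort(sample(genes, n_rewired))
  mats <- lapply(base$multiplex$matrices, function(A) A)
  for (g in rewired) {
    gi <- match(g, genes)
    for (l in seq_along(mats)) {
      A <- mats[[l]]
      nbr <- which(A[gi, ] != 0)
      n_move <- round(rewiring_strength * length(nbr))
      if (n_move == 0L) next
      drop <- nbr[sample.int(length(nbr), n_move)]
      candidates <- setdiff(which(A[gi, ] == 0), gi)
      add <- candidates[sample.int(length(candidates), min(n_move, length(candidates)))]
      A[gi, drop] <- 0; A[drop, gi] <- 0
      A[gi, add] <- 1; A[add, gi] <- 1
      mats[[l]] <- A
    }
  }
  expr_case <- genes
  if (silenced_fraction > 0) {
    pool <- setdiff(genes, rewired)
    silenced <- sample(pool, round(silenced_fraction * length(pool)))
    expr_case <- setdiff(genes, silenced)
  }
  structure(
    list(
      control = base$multiplex,
      case = multiplex_networks(genes, mats, base$multiplex$layer_labels),
      rewired_genes = rewired,
      expression = list(control = genes, case = expr_case),
      params = list(n_rewired = n_rewired, rewiring_strength = rewiring_strength,
                    seed = seed, silenced_fraction = silenced_fraction)
    ),
    class = "condition_pair"
  )
}

#' @export
print.condition_pair <- function(x, ...) {
  cat(sprintf("<condition_pair> %d genes, %d layers, %d planted rewired genes (strength %g)\n",
              length(x$control$gene_index), length(x$control$matrices),
              length(x$rewired_genes), x$params$rewiring_strength))
  invisible(x)
}

#' Simulate annotation sets aligned with planted clusters
#'
#' Each term draws a `coverage` fraction of one cluster's genes plus a
#' `noise` fraction of the remaining genes, giving GMT-writable gene sets
#' whose enrichment in their home clusters is known by construction.
#'
#' @param truth_clusters Named integer vector gene -> cluster.
#' @param n_terms_per_cluster Terms generated per cluster.
#' @param coverage Fraction in `[0, 1]` of the home cluster each term covers.
#' @param noise Fraction in `[0, 1]` of outside genes mixed into each term.
#' @param seed Integer seed.
#' @return Named list mapping term to gene identifiers (possibly empty sets
#'   when `coverage` is 0; [write_gmt()] skips those with a warning).
#' @export
simulate_annotations <- function(truth_clusters, n_terms_per_cluster = 1L,
                                 coverage = 0.8, noise = 0.02, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, noise >= 0, noise <= 1)
  set.seed(seed)
  genes <- names(truth_clusters)
  out <- list()
  for (cl in sort(unique(truth_clusters))) {
    members <- genes[truth_clusters == cl]
    outside <- genes[truth_clusters != cl]
    for (t in seq_len(n_terms_per_cluster)) {
      term <- sprintf("term_c%d_%d", cl, t)
      inside <- sample(members, round(coverage * length(members)))
      extra <- sample(outside, round(noise * length(outside)))
      out[[term]] <- sort(c(inside, extra))
    }
  }
  out
}
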