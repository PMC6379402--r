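#' Partition genes by expression status across a condition pair
#'
#' From binary expression calls in a control and a case (e.g. cancer)
#' condition, splits a gene universe into four disjoint sets that cover it:
#' always-expressed (expressed in both), always-silenced (in neither),
#' case-silenced (control only) and case-activated (case only).
#'
#' @param expr_control,expr_case Character vectors of expressed genes; must
#'   be subsets of `universe`.
#' @param universe Character vector: the full gene universe.
#' @return List with `always_expressed`, `always_silenced`,
#'   `cancer_silenced`, `cancer_activated` (sorted character vectors).
#' @export
partition_genes <- function(expr_control, expr_case, universe) {
  expr_control <- unique(expr_control); expr_case <- unique(expr_case)
  universe <- unique(universe)
  if (!all(expr_control %in% universe) || !all(expr_case %in% universe)) {
    stop("expression sets must be subsets of the gene universe")
  }
  list(
    always_expressed = sort(intersect(expr_control, expr_case)),
    always_silenced = sort(setdiff(universe, union(expr_control, expr_case))),
    cancer_silenced = sort(setdiff(expr_control, expr_case)),
    cancer_activated = sort(setdiff(expr_case, expr_control))
  )
}

#' Rewiring scores between two integrated networks
#'
#' Quantifies how much each gene's local wiring changes between a control
#' and a case integrated network: the graphlet degree vector distance
#' ([gdv_distance()]) between the gene's GDV in the two networks. Genes
#' isolated in both networks score 0. The ranking is most-rewired-first,
#' with ties broken lexicographically by gene identifier.
#'
#' @param icell_control,icell_case [gene_network] objects (typically
#'   `icell_network`s) whose node sets both contain `genes`.
#' @param genes Character vector of genes to score (e.g. the
#'   always-expressed set).
#' @return A `rewiring_ranking` tibble: `gene`, `score`, `rank`, with
#'   attribute `direction = "most_rewired_first"`.
#' @export
rewiring_scores <- function(icell_control, icell_case, genes) {
  missing1 <- setdiff(genes, icell_control$nodes)
  missing2 <- setdiff(genes, icell_case$nodes)
  if (length(missing1) > 0L || length(missing2) > 0L) {
    stop("gene(s) absent from a network's node universe: ",
         paste(utils::head(union(missing1, missing2), 5L), collapse = ", "))
  }
  g1 <- gdv_matrix(count_orbits(icell_control))
  g2 <- gdv_matrix(count_orbits(icell_case))
  w <- orbit_weights()
  score <- vapply(genes, function(g) gdv_distance(g1[g, ], g2[g, ], w), 0)
  ranking_tibble(genes, score, direction = "most_rewired_first")
}

ranking_tibble <- function(genes, score, direction) {
  score <- unname(score)
  ord <- order(-score, genes)
  out <- tibble::tibble(gene = genes[ord], score = score[ord],
                        rank = seq_along(genes))
  structure(out, direction = direction,
            class = c("rewiring_ranking", class(out)))
}

#' Marker enrichment in the most rewired genes
#'
#' Takes the top `top_n` genes of a rewiring ranking and tests their
#' enrichment in a marker list (e.g. known cancer drivers) against a stated
#' background via [gene_set_stats()].
#'
#' @param ranking A `rewiring_ranking` (from [rewiring_scores()] or
#'   [pan_cancer_scores()]).
#' @param top_n Number of top-ranked genes to test (default 500).
#' @param markers Character vector of marker genes.
#' @param background Character vector: the background gene universe the
#'   ranking was drawn from.
#' @return One-row tibble from [gene_set_stats()].
#' @export
top_rewired_enrichment <- function(ranking, top_n = 500L, markers, background) {
  if (top_n > nrow(ranking)) stop("top_n exceeds the ranking length")
  gene_set_stats(ranking$gene[seq_len(top_n)], background, markers)
}

#' Cross-network wiring stability scores
#'
#' For a list of integrated networks (e.g. one per cancer type), scores each
#' gene by the average of its GDV similarities (`1 - GDVD`) over all network
#' pairs. High scores mean the gene keeps the same wiring everywhere; the
#' ranking is least-rewired-first (most similarly wired genes on top), ties
#' broken lexicographically.
#'
#' @param icells List of two or more [gene_network] objects whose node sets
#'   all contain `genes`.
#' @param genes Character vector of genes to score (e.g. genes expressed in
#'   all conditions).
#' @return A `rewiring_ranking` tibble with attribute
#'   `direction = "least_rewired_first"` (scores are similarities in
#'   `(0, 1]`).
#' @export
pan_cancer_scores <- function(icells, genes) {
  if (length(icells) < 2L) stop("need at least two integrated networks")
  for (net in icells) {
    miss <- setdiff(genes, net$nodes)
    if (length(miss) > 0L) {
      stop("gene(s) absent from a network's node universe: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  w <- orbit_weights()
  gdvs <- lapply(icells, function(net) gdv_matrix(count_orbits(net)))
  pairs <- utils::combn(length(icells), 2L)
  sim <- vapply(genes, function(g) {
    mean(vapply(seq_len(ncol(pairs)), function(j) {
      1 - gdv_distance(gdvs[[pairs[1L, j]]][g, ], gdvs[[pairs[2L, j]]][g, ], w)
    }, 0))
  }, 0)
  ranking_tibble(genes, sim, direction = "least_rewired_first")
}

#' Paired fusion and rewiring comparison of two conditions
#'
#' Runs the full condition-comparison protocol: fuse the control multiplex to
#' convergence, then adapt that solution to the case multiplex with a small
#' number of warm-started iterations, build both integrated networks at the
#' same threshold, and score per-gene rewiring. Warm-starting the case
#' factorization from the control solution removes initialization and
#' optimization-path variance from the comparison, so the score differences
#' reflect differences between the two data sets rather than between two
#' independent solver trajectories.
#'
#' @param mx_control,mx_case `multiplex_networks` objects on the same gene
#'   index.
#' @param k Number of clusters for the fusion.
#' @param genes Genes to score (default: the shared gene index).
#' @param threshold_fraction Fraction of each row/column of `G G'` retained
#'   when building the integrated networks.
#' @param max_iter Iterations for the control fit (default 1000).
#' @param adapt_iter Warm-started iterations for the case fit (default 3; a
#'   small number keeps the comparison paired).
#' @param ... Passed to [fuse()].
#' @return List with `ranking` (a `rewiring_ranking`), `icell_control`,
#'   `icell_case`, `fit_control`, `fit_case`.
#' @export
compare_conditions <- function(mx_control, mx_case, k,
                               genes = mx_control$gene_index,
                               threshold_fraction = 0.12,
                               max_iter = 1000L, adapt_iter = 3L, ...) {
  stopifnot(identical(mx_control$gene_index, mx_case$gene_index))
  fit_control <- fuse(mx_control, k = k, max_iter = max_iter, ...)
  fit_case <- fuse(mx_case, k = k, max_iter = adapt_iter,
                   init = fit_control$G, ...)
  ic <- build_icell(fit_control, threshold_fraction = threshold_fraction)
  ix <- build_icell(fit_case, threshold_fraction = threshold_fraction)
  list(
    ranking = rewiring_scores(ic, ix, genes),
    icell_control = ic, icell_case = ix,
    fit_control = fit_control, fit_case = fit_case
  )
}
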