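#' Orbits of the 2- to 4-node graphlets
#'
#' Graphlets are small connected induced subgraphs; orbits are the
#' automorphism-equivalence classes of node positions within them. The 2- to
#' 4-node graphlets have 15 orbits (0-14). Four of these are redundant
#' (linearly determined by the others over any network), leaving the 11
#' non-redundant orbits used for graphlet degree vectors and graphlet
#' correlation matrices.
#'
#' @return `graphlet_orbits()`: integer vector `0:14`.
#'   `nonredundant_orbits()`: the 11 retained orbit numbers.
#'   `redundant_orbits()`: the 4 removed orbit numbers.
#' @export
graphlet_orbits <- function() 0:14

#' @rdname graphlet_orbits
#' @export
redundant_orbits <- function() c(3L, 12L, 13L, 14L)

#' @rdname graphlet_orbits
#' @export
nonredundant_orbits <- function() setdiff(graphlet_orbits(), redundant_orbits())

# Orbit dependency counts o_i (how many orbits affect orbit i, itself
# included) for orbits 0-14, from the graphlet-degree-vector similarity
# methodology's dependency table. They feed the orbit weights
# w_i = 1 - log(o_i)/log(73); the constant 73 is the total orbit count of
# the 2- to 5-node graphlet catalogue the weighting scheme was defined on.
ORBIT_DEPENDENCY_COUNTS <- c(1L, 2L, 2L, 2L, 3L, 4L, 3L, 3L, 4L, 3L, 4L, 4L, 4L, 4L, 3L)

#' Orbit weights for the GDV distance
#'
#' Weight `w_i = 1 - log(o_i)/log(73)` down-weights orbits whose counts are
#' strongly dependent on other orbits' counts (`o_i` = number of orbits that
#' affect orbit `i`). The degree orbit has `o_0 = 1`, so `w_0 = 1`.
#'
#' @param orbits Integer vector of orbit numbers (default: the 11
#'   non-redundant orbits).
#' @return Named numeric vector of weights in `(0, 1]`.
#' @export
orbit_weights <- function(orbits = nonredundant_orbits()) {
  stopifnot(all(orbits %in% graphlet_orbits()))
  o <- ORBIT_DEPENDENCY_COUNTS[orbits + 1L]
  w <- 1 - log(o) / log(73)
  names(w) <- paste0("orbit", orbits)
  w
}

#' Count graphlet orbits per node
#'
#' Exact counts of each node's appearances at orbits 0-14 of the 2- to
#' 4-node graphlets, by enumeration of connected induced subgraphs (every
#' 3- and 4-node connected induced subgraph is visited exactly once).
#' Isolated nodes get all-zero rows; the orbit-0 count is the node degree.
#'
#' @param net A [gene_network].
#' @return A tibble with column `gene` and integer columns `orbit0` ...
#'   `orbit14`, rows in the network's node order.
#' @export
count_orbits <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- n_nodes(net)
  if (n == 0L) {
    return(tibble::tibble(gene = character())[, "gene", drop = FALSE])
  }
  if (n_edges(net) == 0L) {
    counts <- matrix(0L, n, 15L)
  } else {
    e <- cbind(match(net$edges[, 1L], net$nodes), match(net$edges[, 2L], net$nodes)) - 1L
    storage.mode(e) <- "integer"
    counts <- .count_orbits_cpp(e, n)
  }
  colnames(counts) <- paste0("orbit", 0:14)
  dplyr::bind_cols(tibble::tibble(gene = net$nodes), tibble::as_tibble(counts))
}

#' Extract the non-redundant GDV matrix from an orbit-count table
#'
#' @param gdv_table Output of [count_orbits()].
#' @return Numeric matrix, genes x 11 non-redundant orbits, gene names as
#'   row names.
#' @export
gdv_matrix <- function(gdv_table) {
  cols <- paste0("orbit", nonredundant_orbits())
  m <- as.matrix(gdv_table[, cols])
  rownames(m) <- gdv_table$gene
  m
}

#' Graphlet degree vector distance (GDVD)
#'
#' Weighted log-scale distance between two graphlet degree vectors. The
#' per-orbit distance is
#' `D_i = w_i * |log(h_i + 1) - log(c_i + 1)| / log(max(h_i, c_i) + 2)`
#' and the total distance is `sum(D_i) / sum(w_i)`, which lies in `[0, 1)`:
#' 0 means identical vectors and the denominator choice keeps every
#' per-orbit term strictly below its weight.
#'
#' @param h,c Non-negative integer vectors of equal length (orbit counts;
#'   by default the 11 non-redundant orbits).
#' @param weights Orbit weights; default [orbit_weights()].
#' @return Distance in `[0, 1)`.
#' @export
gdv_distance <- function(h, c, weights = orbit_weights()) {
  if (length(h) != length(c) || length(h) != length(weights)) {
    stop("GDVs and weights must have equal length")
  }
  if (any(h < 0) || any(c < 0)) stop("negative orbit counts")
  d <- weights * abs(log(h + 1) - log(c + 1)) / log(pmax(h, c) + 2)
  sum(d) / sum(weights)
}

#' Graphlet correlation matrix (GCM)
#'
#' Spearman correlations between the 11 non-redundant orbit-count columns
#' over all nodes of a network. One artificial all-ones GDV row is appended
#' before correlating so constant columns (e.g. no 4-cliques anywhere) do not
#' produce undefined correlations; ties get average ranks.
#'
#' @param net A [gene_network], or a precomputed orbit-count tibble from
#'   [count_orbits()].
#' @return An 11 x 11 symmetric correlation matrix with unit diagonal,
#'   dimnames `orbit0`, `orbit1`, ...
#' @export
graphlet_correlation_matrix <- function(net) {
  tab <- if (inherits(net, "gene_network")) count_orbits(net) else net
  m <- gdv_matrix(tab)
  if (nrow(m) < 2L) stop("need at least 2 nodes for a correlation matrix")
  m <- rbind(m, 1)   # artificial all-ones GDV guards against constant columns
  gcm <- stats::cor(m, method = "spearman")
  (gcm + t(gcm)) / 2
}

#' Graphlet correlation distance between two networks (GCD-11)
#'
#' Euclidean distance between the 55 strictly-upper-triangle entries of the
#' two networks' graphlet correlation matrices. Symmetric in its arguments;
#' 0 for isomorphic networks.
#'
#' @param net1,net2 [gene_network] objects (or orbit-count tibbles).
#' @return Non-negative distance.
#' @export
gcd11 <- function(net1, net2) {
  g1 <- graphlet_correlation_matrix(net1)
  g2 <- graphlet_correlation_matrix(net2)
  up <- upper.tri(g1)
  sqrt(sum((g1[up] - g2[up])^2))
}
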