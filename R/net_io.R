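#' Construct a gene network
#'
#' A `gene_network` is a simple undirected graph over gene identifiers:
#' no self-loops, no duplicate edges, every edge endpoint listed among the
#' nodes. Gene identifiers are opaque, case-sensitive strings; no identifier
#' mapping is performed.
#'
#' @param nodes Character vector of gene identifiers (order is preserved).
#' @param edges Two-column character matrix or data frame of edges. Self-loops
#'   are dropped; duplicate and reversed-duplicate edges are collapsed.
#' @param layer_label Optional label naming the data layer (e.g. `"ppi"`).
#' @return A `gene_network` object: a list with elements `nodes` (character)
#'   and `edges` (two-column character matrix, endpoints sorted within each
#'   row) plus a `layer_label` attribute.
#' @examples
#' net <- gene_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' n_edges(net)
#' @export
gene_network <- function(nodes, edges = NULL, layer_label = "") {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) nodes <- unique(nodes)
  if (any(!nzchar(nodes))) stop("empty gene identifier in node list")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop("edges must have two columns")
    edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
    edges <- canonical_edges(edges)
    missing <- setdiff(c(edges), nodes)
    if (length(missing) > 0L) {
      stop("edge endpoint(s) not in node list: ", paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  structure(
    list(nodes = nodes, edges = edges),
    layer_label = as.character(layer_label)[1L],
    class = "gene_network"
  )
}

# Canonicalize: sort endpoints within each edge, drop self-loops and duplicates.
canonical_edges <- function(edges) {
  if (NROW(edges) == 0L) return(matrix(character(), ncol = 2L))
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  cbind(a[!dup], b[!dup])
}

edge_keys <- function(net) {
  if (n_edges(net) == 0L) return(character())
  paste(net$edges[, 1L], net$edges[, 2L], sep = "\r")
}

#' @rdname gene_network
#' @param x,net A `gene_network`.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname gene_network
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname gene_network
#' @export
layer_label <- function(net) attr(net, "layer_label")

#' @export
print.gene_network <- function(x, ...) {
  lab <- layer_label(x)
  cat(sprintf(
    "<gene_network%s> %d nodes, %d edges\n",
    if (nzchar(lab)) paste0(" ", lab) else "", n_nodes(x), n_edges(x)
  ))
  invisible(x)
}

#' @export
tidy.gene_network <- function(x, ...) {
  tibble::tibble(from = x$edges[, 1L], to = x$edges[, 2L])
}

#' Convert a gene network to an igraph graph
#'
#' @param net A `gene_network`.
#' @return An [igraph::graph] with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n_nodes(net), name = net$nodes)
  if (n_edges(net) > 0L) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Read an edge list from a TSV file
#'
#' Lines hold two whitespace- or tab-separated gene identifiers; extra columns
#' are ignored; lines starting with `#` are comments. Self-loops are dropped
#' and duplicate (including reversed) edges collapsed. Node order is
#' first-appearance order. An empty file yields an empty network.
#'
#' @param path Path to the edge-list file.
#' @param layer_label Label for the layer the file encodes.
#' @return A [gene_network].
#' @export
read_edge_list <- function(path, layer_label = "") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(gene_network(character(), NULL, layer_label))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list line %d in '%s': fewer than 2 fields", idx[bad[1L]], path))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  nodes <- unique(c(rbind(a, b)))   # first-appearance order, interleaved
  gene_network(nodes, cbind(a, b), layer_label)
}

#' Write an edge list to a TSV file
#'
#' @param net A [gene_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  con <- file(path, "w")
  on.exit(close(con))
  if (n_edges(net) > 0L) {
    writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), con)
  }
  invisible(path)
}

#' Restrict a network to genes expressed in a tissue
#'
#' Keeps the induced subgraph on the expressed genes: a node survives iff it
#' is expressed, an edge iff both endpoints are. This is how tissue-specific
#' molecular networks are built from binary expression calls.
#'
#' @param net A [gene_network].
#' @param expressed Character vector of expressed gene identifiers.
#' @return The induced [gene_network] (possibly empty).
#' @export
make_tissue_specific <- function(net, expressed) {
  stopifnot(inherits(net, "gene_network"))
  expressed <- as.character(expressed)
  nodes <- net$nodes[net$nodes %in% expressed]
  e <- net$edges
  if (NROW(e) > 0L) {
    keep <- e[, 1L] %in% expressed & e[, 2L] %in% expressed
    e <- e[keep, , drop = FALSE]
  }
  gene_network(nodes, e, layer_label(net))
}

#' Align networks onto one shared gene index
#'
#' Builds the aligned multiplex representation required by the fusion model:
#' one shared, lexicographically sorted gene index and one 0/1 symmetric
#' adjacency matrix per layer (zero diagonal), with absent nodes appearing as
#' zero rows/columns under the union policy.
#'
#' @param nets List of [gene_network] objects (one per layer).
#' @param node_policy `"union"` (default) or `"intersection"` of node sets.
#' @param anchor Optional layer label or index: genes absent from the anchor
#'   layer's node set are dropped before alignment (e.g. keep only genes with
#'   at least one physical interaction). `NULL` disables the filter.
#' @return A `multiplex_networks` object: list with `gene_index` (character),
#'   `matrices` (list of n x n 0/1 matrices), `layer_labels`.
#' @export
align_networks <- function(nets, node_policy = c("union", "intersection"), anchor = NULL) {
  stopifnot(length(nets) >= 1L, all(vapply(nets, inherits, TRUE, "gene_network")))
  node_policy <- match.arg(node_policy)
  labels <- vapply(seq_along(nets), function(i) {
    lab <- layer_label(nets[[i]])
    if (nzchar(lab)) lab else paste0("layer", i)
  }, "")
  node_sets <- lapply(nets, `[[`, "nodes")
  idx <- if (node_policy == "union") Reduce(union, node_sets) else Reduce(intersect, node_sets)
  if (node_policy == "intersection" && length(idx) == 0L) {
    stop("intersection of layer node sets is empty")
  }
  if (!is.null(anchor)) {
    ai <- if (is.character(anchor)) match(anchor, labels) else as.integer(anchor)
    if (is.na(ai) || ai < 1L || ai > length(nets)) stop("anchor layer not found: ", anchor)
    idx <- idx[idx %in% node_sets[[ai]]]
    if (length(idx) == 0L) stop("no genes left after anchor-layer filter")
  }
  idx <- sort(idx)
  mats <- lapply(nets, adjacency_on_index, gene_index = idx)
  names(mats) <- labels
  multiplex_networks(idx, mats, labels)
}

adjacency_on_index <- function(net, gene_index) {
  n <- length(gene_index)
  A <- matrix(0, n, n, dimnames = list(gene_index, gene_index))
  e <- net$edges
  if (NROW(e) > 0L) {
    i <- match(e[, 1L], gene_index)
    j <- match(e[, 2L], gene_index)
    keep <- !is.na(i) & !is.na(j)
    A[cbind(i[keep], j[keep])] <- 1
    A[cbind(j[keep], i[keep])] <- 1
  }
  A
}

#' Bundle aligned adjacency matrices into a multiplex object
#'
#' @param gene_index Character vector of gene identifiers (shared node order).
#' @param matrices List of symmetric 0/1 adjacency matrices on that index.
#' @param layer_labels Character vector of layer names.
#' @return A `multiplex_networks` object.
#' @export
multiplex_networks <- function(gene_index, matrices, layer_labels = names(matrices)) {
  n <- length(gene_index)
  for (A in matrices) {
    stopifnot(nrow(A) == n, ncol(A) == n)
    if (max(abs(A - t(A))) > 0) stop("adjacency matrix not symmetric")
    if (any(diag(A) != 0)) stop("adjacency matrix has nonzero diagonal")
  }
  if (is.null(layer_labels)) layer_labels <- paste0("layer", seq_along(matrices))
  structure(
    list(gene_index = gene_index, matrices = matrices, layer_labels = layer_labels),
    class = "multiplex_networks"
  )
}

#' @export
print.multiplex_networks <- function(x, ...) {
  cat(sprintf(
    "<multiplex_networks> %d genes, %d layers (%s); edges per layer: %s\n",
    length(x$gene_index), length(x$matrices),
    paste(x$layer_labels, collapse = ", "),
    paste(vapply(x$matrices, function(A) sum(A) / 2, 0), collapse = ", ")
  ))
  invisible(x)
}

#' Recover one layer of a multiplex as a gene network
#'
#' @param mx A `multiplex_networks`.
#' @param layer Layer index or label.
#' @return A [gene_network] on the full shared gene index.
#' @export
layer_network <- function(mx, layer = 1L) {
  if (is.character(layer)) layer <- match(layer, mx$layer_labels)
  A <- mx$matrices[[layer]]
  adjacency_to_network(A, mx$gene_index, mx$layer_labels[[layer]])
}

adjacency_to_network <- function(A, gene_index, label = "") {
  ij <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  gene_network(gene_index, cbind(gene_index[ij[, 1L]], gene_index[ij[, 2L]]), label)
}

#' Edge-set Jaccard overlap of two networks
#'
#' Fraction of shared edges among all edges, over unordered gene pairs:
#' `|E1 n E2| / |E1 u E2|`. Used to quantify how rarely two molecular data
#' layers report the same interactions.
#'
#' @param net1,net2 [gene_network] objects.
#' @return A number in `[0, 1]`; if both edge sets are empty, returns 0 with
#'   a warning.
#' @export
edge_jaccard <- function(net1, net2) {
  k1 <- edge_keys(net1); k2 <- edge_keys(net2)
  u <- length(union(k1, k2))
  if (u == 0L) {
    warning("both networks have empty edge sets; Jaccard undefined, returning 0")
    return(0)
  }
  length(intersect(k1, k2)) / u
}

#' Union of several networks
#'
#' Node set and edge set unions; the simple baseline integration a fused
#' network is compared against.
#'
#' @param nets List of [gene_network] objects.
#' @param layer_label Label for the result.
#' @return A [gene_network].
#' @export
union_network <- function(nets, layer_label = "union") {
  stopifnot(length(nets) >= 1L)
  nodes <- Reduce(union, lapply(nets, `[[`, "nodes"))
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  gene_network(nodes, edges, layer_label)
}

#' Read a binary expression table
#'
#' TSV with gene identifiers in the first column and one column per tissue,
#' cells in {0, 1} (expressed / not expressed, as in antibody-staining calls).
#'
#' @param path Path to the table.
#' @return An expression profile: named list mapping tissue to the character
#'   vector of expressed genes.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  genes <- as.character(tab[[1L]])
  out <- lapply(tab[-1L], function(col) genes[as.numeric(col) != 0])
  names(out) <- names(tab)[-1L]
  out
}

#' Write a binary expression table
#'
#' @param profile Named list mapping tissue to expressed gene identifiers.
#' @param genes Character vector: the gene universe (rows of the table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(profile, genes, path) {
  tab <- data.frame(gene = genes, check.names = FALSE)
  for (tis in names(profile)) tab[[tis]] <- as.integer(genes %in% profile[[tis]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation sets in GMT format
#'
#' Each line: term, description, then member gene identifiers, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list mapping term to character vector of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", substr(ln, 1, 40))
    out[[f[1L]]] <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
  }
  out
}

#' Write gene annotation sets in GMT format
#'
#' Empty terms are skipped with a warning.
#'
#' @param annotations Named list mapping term to gene identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  empty <- vapply(annotations, length, 1L) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty annotation term(s)")
    annotations <- annotations[!empty]
  }
  lines <- vapply(names(annotations), function(term) {
    paste(c(term, term, annotations[[term]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a plain gene list (one identifier per line)
#'
#' @param path File path.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
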