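test_that("edge lists are canonicalized: self-loops dropped, duplicates collapsed", {
  path <- withr::local_tempfile()
  writeLines(c("a\tb", "b\ta", "a\ta"), path)
  net <- read_edge_list(path)
  expect_setequal(net$nodes, c("a", "b"))
  expect_equal(n_edges(net), 1L)

  writeLines(c("# comment", "a b", "b c", "a c"), path)
  tri <- read_edge_list(path)
  expect_equal(n_nodes(tri), 3L)
  expect_equal(n_edges(tri), 3L)
})

test_that("malformed lines are reported with their line number; empty file is empty network", {
  path <- withr::local_tempfile()
  writeLines(c("a\tb", "lonely"), path)
  expect_error(read_edge_list(path), "line 2")
  writeLines(character(), path)
  empty <- read_edge_list(path)
  expect_equal(n_nodes(empty), 0L)
  expect_equal(n_edges(empty), 0L)
})

test_that("write/read round-trip preserves node and edge sets exactly", {
  net <- random_test_network(50, 0.08, seed = 42)
  path <- withr::local_tempfile()
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_setequal(back$nodes[back$nodes %in% c(net$edges)], unique(c(net$edges)))
  expect_setequal(paste(back$edges[, 1], back$edges[, 2]),
                  paste(net$edges[, 1], net$edges[, 2]))
})

test_that("tissue-specific restriction keeps the induced subgraph and is idempotent", {
  tri <- gene_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  sub <- make_tissue_specific(tri, c("a", "b"))
  expect_equal(sub$nodes, c("a", "b"))
  expect_equal(n_edges(sub), 1L)
  # superset of nodes leaves the network unchanged
  same <- make_tissue_specific(tri, c("a", "b", "c", "zzz"))
  expect_equal(same$edges, tri$edges)
  # brute-force filter oracle on a random graph
  net <- random_test_network(100, 0.05, seed = 7)
  set.seed(8)
  keep <- sample(net$nodes, 50)
  expected <- sum(net$edges[, 1] %in% keep & net$edges[, 2] %in% keep)
  got <- make_tissue_specific(net, keep)
  expect_equal(n_edges(got), expected)
  # idempotence
  twice <- make_tissue_specific(got, keep)
  expect_equal(twice$edges, got$edges)
})

test_that("alignment produces symmetric zero-diagonal matrices matching degrees", {
  n1 <- gene_network(c("a", "b"), rbind(c("a", "b")), "x")
  n2 <- gene_network(c("b", "c"), rbind(c("b", "c")), "y")
  mx <- align_networks(list(n1, n2), "union")
  expect_equal(mx$gene_index, c("a", "b", "c"))
  expect_equal(sum(mx$matrices[[1]]["c", ]), 0)
  expect_error(align_networks(list(n1, gene_network("z")), "intersection"),
               "empty")
  # three random layers: row sums equal each layer's degree sequence
  nets <- lapply(1:3, function(s) random_test_network(40, 0.1, seed = s))
  mx3 <- align_networks(nets, "union")
  for (i in 1:3) {
    expect_true(isSymmetric(mx3$matrices[[i]]))
    expect_true(all(diag(mx3$matrices[[i]]) == 0))
    deg <- node_degrees(nets[[i]])
    expect_equal(rowSums(mx3$matrices[[i]])[names(deg)], deg + 0,
                 ignore_attr = TRUE)
  }
})

test_that("anchor-layer filter keeps only genes present in the anchor layer", {
  n1 <- gene_network(c("a", "b"), rbind(c("a", "b")), "ppi")
  n2 <- gene_network(c("b", "c"), rbind(c("b", "c")), "coex")
  mx <- align_networks(list(n1, n2), "union", anchor = "ppi")
  expect_equal(mx$gene_index, c("a", "b"))
})

test_that("edge Jaccard matches set arithmetic", {
  e1 <- gene_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  e2 <- gene_network(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  expect_equal(edge_jaccard(e1, e1), 1)
  expect_equal(edge_jaccard(e1, e2), 1 / 3)
  disjoint <- gene_network(c("x", "y"), rbind(c("x", "y")))
  expect_equal(edge_jaccard(e1, disjoint), 0)
  expect_warning(res <- edge_jaccard(gene_network("a"), gene_network("b")), "empty")
  expect_equal(res, 0)
})

test_that("union of networks unions node and edge sets", {
  k2a <- gene_network(c("a", "b"), rbind(c("a", "b")))
  k2b <- gene_network(c("c", "d"), rbind(c("c", "d")))
  u <- union_network(list(k2a, k2b))
  expect_equal(n_nodes(u), 4L)
  expect_equal(n_edges(u), 2L)
  expect_equal(union_network(list(k2a))$edges, k2a$edges)
  t1 <- gene_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  t2 <- gene_network(c("b", "c", "d"), rbind(c("b", "c"), c("c", "d"), c("b", "d")))
  u2 <- union_network(list(t1, t2))
  expect_equal(n_nodes(u2), 4L)
  expect_equal(n_edges(u2), 5L)
})

test_that("expression tables, GMT annotations and gene lists round-trip", {
  dir <- withr::local_tempdir()
  genes <- c("g1", "g2", "g3")
  prof <- list(control = c("g1", "g2"), case = c("g2", "g3"))
  p1 <- file.path(dir, "expr.tsv")
  write_expression(prof, genes, p1)
  expect_equal(read_expression(p1), prof)
  ann <- list(tA = c("g1", "g2"), tB = "g3")
  p2 <- file.path(dir, "ann.gmt")
  write_gmt(ann, p2)
  expect_equal(read_gmt(p2), ann)
  expect_warning(write_gmt(c(ann, list(tC = character())), p2), "empty")
  p3 <- file.path(dir, "genes.txt")
  write_gene_list(genes, p3)
  expect_equal(read_gene_list(p3), genes)
})
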