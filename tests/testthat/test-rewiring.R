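test_that("expression partition is a disjoint cover of the universe", {
  p <- partition_genes(c("a", "b"), c("b", "c"), c("a", "b", "c", "d"))
  expect_equal(p$always_expressed, "b")
  expect_equal(p$cancer_silenced, "a")
  expect_equal(p$cancer_activated, "c")
  expect_equal(p$always_silenced, "d")
  # full expression in both conditions
  u <- sprintf("g%d", 1:10)
  p_all <- partition_genes(u, u, u)
  expect_setequal(p_all$always_expressed, u)
  expect_length(p_all$always_silenced, 0L)
  # both empty
  p_none <- partition_genes(character(), character(), u)
  expect_setequal(p_none$always_silenced, u)
  # disjoint cover property on random sets
  set.seed(41)
  for (i in 1:5) {
    ec <- sample(u, sample(0:10, 1))
    ex <- sample(u, sample(0:10, 1))
    pp <- partition_genes(ec, ex, u)
    all_genes <- unlist(pp, use.names = FALSE)
    expect_setequal(all_genes, u)
    expect_equal(anyDuplicated(all_genes), 0L)
  }
  expect_error(partition_genes(c("zzz"), u, u), "subsets")
})

test_that("rewiring scores are zero on identical networks and bounded", {
  net <- random_test_network(40, 0.1, seed = 42)
  r <- rewiring_scores(net, net, net$nodes)
  expect_true(all(r$score == 0))
  expect_true(all(r$score >= 0 & r$score < 1))
  expect_equal(r$gene, sort(net$nodes))   # tie-break: lexicographic
  expect_error(rewiring_scores(net, net, "missing_gene"), "missing_gene")
})

test_that("a single-edge difference scores the hand-computed GDVD", {
  ctrl <- gene_network(c("a", "b"), rbind(c("a", "b")))
  case <- gene_network(c("a", "b"))
  r <- rewiring_scores(ctrl, case, c("a", "b"))
  o <- c(1, 2, 2, 3, 4, 3, 3, 4, 3, 4, 4)
  w <- 1 - log(o) / log(73)
  expect_equal(r$score, rep(w[1] * (log(2) / log(3)) / sum(w), 2))
})

test_that("top-rewired marker enrichment delegates with validation", {
  set.seed(43)
  background <- sprintf("g%03d", 1:200)
  score <- setNames(runif(200), background)
  ranking <- rewiring_scores(
    random_test_network(5, 0.5, seed = 1),
    random_test_network(5, 0.5, seed = 2),
    sprintf("n%02d", 1:5)
  )
  expect_error(top_rewired_enrichment(ranking, top_n = 10, markers = "x",
                                      background = "x"),
               "exceeds")
  # markers exactly equal to the top prefix maximize fold
  pm <- simulate_multiplex(100, 2, 1, 0.5, 0.1, seed = 44)
  cp <- simulate_condition_pair(pm, 10, 0.9, seed = 45)
  rk <- rewiring_scores(layer_network(cp$control, 1), layer_network(cp$case, 1),
                        cp$control$gene_index)
  top <- rk$gene[1:10]
  res <- top_rewired_enrichment(rk, top_n = 10, markers = top,
                                background = cp$control$gene_index)
  expect_equal(res$X, 10L)
  expect_equal(res$fold, (10 / 10) / (10 / 100))
  # random markers: fold near 1 in expectation
  folds <- vapply(1:100, function(s) {
    set.seed(s + 500)
    mk <- sample(cp$control$gene_index, 30)
    top_rewired_enrichment(rk, top_n = 50, markers = mk,
                           background = cp$control$gene_index)$fold
  }, 0)
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("cross-network similarity is one on identical networks and finds stable genes", {
  net <- random_test_network(30, 0.15, seed = 46)
  r <- pan_cancer_scores(list(net, net, net), net$nodes)
  expect_true(all(r$score == 1))
  expect_error(pan_cancer_scores(list(net), net$nodes), "at least two")
  # gene isolated in one network, degree-1 in the other: similarity = 1 - hand GDVD
  a <- gene_network(c("x", "y", "z"), rbind(c("x", "y")))
  b <- gene_network(c("x", "y", "z"), rbind(c("y", "z")))
  r2 <- pan_cancer_scores(list(a, b), c("x", "y", "z"))
  o <- c(1, 2, 2, 3, 4, 3, 3, 4, 3, 4, 4)
  w <- 1 - log(o) / log(73)
  expect_equal(r2$score[r2$gene == "x"],
               1 - w[1] * (log(2) / log(3)) / sum(w))
  # planted stability: genes with frozen neighborhoods across replicate networks
  # rank at the top of the similarity ordering
  set.seed(47)
  n <- 60
  nodes <- sprintf("s%02d", 1:n)
  stable <- nodes[1:10]
  make_net <- function(seed) {
    set.seed(seed)
    # fixed star among stable genes plus random noise among the rest
    fixed <- cbind(stable[1:9], stable[c(2:10)])
    g <- igraph::sample_gnp(n - 10, 0.1)
    el <- igraph::as_edgelist(g)
    noise <- cbind(nodes[10 + el[, 1]], nodes[10 + el[, 2]])
    gene_network(nodes, rbind(fixed, noise))
  }
  nets <- lapply(1:5, make_net)
  r3 <- pan_cancer_scores(nets, nodes)
  expect_gte(sum(r3$gene[1:10] %in% stable), 8)
})
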