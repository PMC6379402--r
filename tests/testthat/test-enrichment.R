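test_that("hypergeometric tails match exact combinatorial sums", {
  expect_equal(hypergeom_enrichment_p(0, 4, 5, 10), 1)
  expect_equal(hypergeom_enrichment_p(4, 4, 5, 10), 5 / 210)
  expect_equal(depletion_p(0, 4, 5, 10), 5 / 210)
  expect_equal(depletion_p(4, 4, 5, 10), 1)
  set.seed(12)
  for (i in 1:200) {
    M <- sample(10:60, 1)
    N <- sample(1:M, 1)
    K <- sample(1:M, 1)
    X <- sample(max(0, N + K - M):min(N, K), 1)
    expect_equal(hypergeom_enrichment_p(X, N, K, M),
                 brute_force_enrichment_p(X, N, K, M), tolerance = 1e-12)
    expect_equal(depletion_p(X, N, K, M),
                 brute_force_depletion_p(X, N, K, M), tolerance = 1e-12)
    # complementary cumulative identity
    if (X >= 1) {
      expect_equal(hypergeom_enrichment_p(X, N, K, M) + depletion_p(X - 1, N, K, M),
                   1, tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_enrichment_p(5, 4, 5, 10), "bounds")
})

test_that("fold enrichment follows its definition and error contract", {
  expect_equal(fold_enrichment(4, 4, 5, 10), 2)
  expect_equal(fold_enrichment(2, 4, 5, 10), 1)
  expect_equal(fold_enrichment(0, 4, 5, 10), 0)
  expect_error(fold_enrichment(0, 0, 5, 10), "N = 0")
  expect_error(fold_enrichment(0, 4, 0, 10), "undefined")
})

test_that("BH adjustment is a step-up, order-preserving, permutation-invariant", {
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], adj)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster enrichment covers all genes when terms equal clusters", {
  pm <- simulate_multiplex(60, 3, 1, 1, 0, seed = 2)
  ann <- simulate_annotations(pm$truth, coverage = 1, noise = 0, seed = 2)
  res <- cluster_enrichment(pm$truth, ann, alpha = 0.05)
  expect_equal(res$percent_covered, 100)
  expect_true(all(c("cluster", "term", "X", "N", "K", "M", "fold",
                    "p_raw", "p_adjusted", "enriched") %in% names(res$table)))
  expect_error(cluster_enrichment(pm$truth, list()), "no annotated genes")
})

test_that("cluster coverage counts only a gene's own enriched annotations", {
  clustering <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  # termA matches cluster 1 exactly; g 'f' carries only an unenriched term
  ann <- list(termA = c("a", "b", "c"), termB = "f")
  res <- cluster_enrichment(clustering, ann, alpha = 0.05)
  expect_true("f" %in% names(clustering))
  tabB <- res$table[res$table$term == "termB" & res$table$cluster == 2, ]
  if (!tabB$enriched) {
    # f annotated but its only term not enriched: in denominator, not numerator
    expect_lt(res$percent_covered, 100)
  }
  # coverage percentage is monotone in alpha
  res_hi <- cluster_enrichment(clustering, ann, alpha = 1)
  expect_gte(res_hi$percent_covered, res$percent_covered)
})

test_that("gene-set marker statistics route by fold and validate inputs", {
  background <- sprintf("g%04d", 1:1000)
  markers <- background[1:50]
  set <- c(background[1:30], background[101:170])   # 30 of 50 markers in 100 genes
  res <- gene_set_stats(set, background, markers)
  expect_equal(res$fold, (30 / 100) / (50 / 1000))
  expect_equal(res$direction, "enriched")
  expect_equal(res$p, brute_force_enrichment_p(30, 100, 50, 1000), tolerance = 1e-12)
  depl <- gene_set_stats(background[101:200], background, markers)
  expect_equal(depl$direction, "depleted")
  expect_error(gene_set_stats(c("zzz"), background, markers), "subset")
  expect_error(gene_set_stats(set, background, c("not_there")), "K = 0")
  full <- gene_set_stats(background, background, markers)
  expect_equal(full$fold, 1)
  expect_equal(full$p, 1)
})

test_that("empirical permutation p-value is (r+1)/(n+1)", {
  expect_equal(empirical_permutation_p(0, 1000), 1 / 1001)
  expect_equal(empirical_permutation_p(9, 99), 0.1)
  expect_equal(empirical_permutation_p(5, 5), 1)
  expect_error(empirical_permutation_p(6, 5), "r <= n")
})
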