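mx_from_matrix <- function(A, genes = sprintf("g%d", seq_len(nrow(A)))) {
  dimnames(A) <- list(genes, genes)
  multiplex_networks(genes, list(A))
}

test_that("SVD initialization matches the hand eigen-decomposition of an edge", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  mx <- mx_from_matrix(A)
  G <- init_svd(mx, 1)
  # singular value 1, left vector (1,1)/sqrt(2): column = 1 * (0.7071, 0.7071)
  expect_equal(as.vector(G), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_true(all(G >= 0))
})

test_that("SVD initialization is non-negative and sign-invariant; rank overflow warns", {
  pm <- simulate_multiplex(40, 2, 2, 0.6, 0.05, seed = 3)
  G <- init_svd(pm$multiplex, 4)
  expect_true(all(G >= 0))
  # a 3-node path has adjacency rank 2: asking for 3 columns zero-pads one
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_warning(G3 <- init_svd(mx_from_matrix(p3), 3), "rank")
  expect_equal(sum(G3[, 3]), 0)
})

test_that("the closed-form S update matches hand linear algebra", {
  # G = identity: S recovers A up to the epsilon ridge
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  S <- update_s(A, diag(2))
  expect_equal(S, A, tolerance = 1e-6)
  expect_equal(update_s(matrix(0, 2, 2), diag(2)), matrix(0, 2, 2), tolerance = 1e-12)
  # one-hot indicator of {1,2}, {3,4} with edges (1,2), (3,4):
  # G'G = diag(2,2), G'AG = diag(2,2), S = diag(0.5, 0.5)
  G <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  A4 <- matrix(0, 4, 4)
  A4[1, 2] <- A4[2, 1] <- 1
  A4[3, 4] <- A4[4, 3] <- 1
  expect_equal(update_s(A4, G), diag(c(0.5, 0.5)), tolerance = 1e-6)
  expect_error(update_s(A4, diag(3)), "shape")
})

test_that("the multiplicative update preserves non-negativity and decreases RSE", {
  pm <- simulate_multiplex(60, 4, 2, 0.4, 0.05, seed = 5)
  mx <- pm$multiplex
  G <- init_random(mx, 4, seed = 9)
  for (it in 1:50) {
    S <- lapply(mx$matrices, update_s, G = G)
    before <- rse(mx, G, S)
    G <- update_g(mx, S, G)
    expect_true(all(G >= 0))
    S2 <- lapply(mx$matrices, update_s, G = G)
    expect_lte(rse(mx, G, S2), before + 1e-9)
  }
})

test_that("an exact factorization is a fixed point of the update", {
  pm <- simulate_multiplex(30, 3, 2, 1, 0, seed = 1)
  mx <- pm$multiplex
  # strictly positive soft indicators reproducing the planted blocks
  G0 <- outer(pm$truth, 1:3, `==`) + 0.01
  S0 <- lapply(mx$matrices, update_s, G = G0)
  r0 <- rse(mx, G0, S0)
  G1 <- update_g(mx, S0, G0)
  S1 <- lapply(mx$matrices, update_s, G = G1)
  expect_lt(abs(rse(mx, G1, S1) - r0), 1e-6)
})

test_that("RSE matches a brute-force elementwise evaluation", {
  set.seed(7)
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  mx <- mx_from_matrix(A)
  G <- matrix(runif(6), 3, 2)
  S <- list(matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2))
  recon <- G %*% S[[1]] %*% t(G)
  manual <- sum((A - recon)^2) / sum(A^2)
  expect_equal(rse(mx, G, S), manual, tolerance = 1e-12)
  expect_equal(rse(mx, matrix(0, 3, 2), list(matrix(0, 2, 2))), 1)
  expect_error(rse(mx_from_matrix(matrix(0, 2, 2)), diag(2), list(diag(2))),
               "empty")
})

test_that("fuse yields a non-increasing RSE trace and attains the block-structure optimum", {
  pm <- simulate_multiplex(12, 3, 2, 1, 0, seed = 1)   # three disjoint 4-cliques
  fit <- fuse(pm$multiplex, k = 3, max_iter = 200)
  expect_true(all(diff(fit$rse_trace) <= 1e-9))
  # analytic optimum for rank-1-per-block fits of a zero-diagonal 4-clique:
  # min_c ||(J - I) - cJ||^2 = 3 at c = 3/4, so RSE = 3/12 = 0.25 per block
  expect_lt(fit$rse_trace[fit$iterations], 0.25 + 1e-3)
  expect_true(all(fit$G >= 0))
  # and the planted blocks are recovered exactly (up to label permutation)
  expect_equal(association_matrix(hard_cluster(fit)),
               association_matrix(pm$truth))
  for (S in fit$S) expect_equal(S, t(S), tolerance = 1e-10)
  # identity start at k = n is already exact
  mx <- pm$multiplex
  fit_id <- fuse(mx, k = 12, max_iter = 1, init = diag(12))
  expect_lt(fit_id$rse_trace[1], 1e-10)
})

test_that("tidy and glance summarize a fusion fit", {
  pm <- simulate_multiplex(20, 2, 2, 0.8, 0.05, seed = 4)
  fit <- fuse(pm$multiplex, k = 2, max_iter = 20)
  td <- tidy(fit)
  expect_equal(nrow(td), 40L)
  expect_named(td, c("gene", "cluster", "weight"))
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_equal(gl$iterations, 20L)
})

test_that("iCell thresholding keeps top row/column entries with ties, symmetric", {
  # hand case: W from one-hot-ish G, q chosen to keep the top entry per row
  G <- rbind(c(0.9, 0.3), c(1, 0), c(0.5, 0.8))
  rownames(G) <- c("a", "b", "c")
  W <- tcrossprod(G); diag(W) <- 0
  # q = 0.34 on n = 3 keeps ceil(0.34*2) = 1 entry per row
  ic <- build_icell(G, c("a", "b", "c"), threshold_fraction = 0.34)
  keys <- paste(ic$edges[, 1], ic$edges[, 2])
  # row maxima: a->b (0.9), b->a (0.9), c->a (0.69): edges ab and ac
  expect_setequal(keys, c("a b", "a c"))
  # q = 1 yields the complete graph over positive entries
  full <- build_icell(G, c("a", "b", "c"), threshold_fraction = 1)
  expect_equal(n_edges(full), 3L)
})

test_that("one-hot factors give an iCell confined to clusters and a bounded edge count", {
  pm <- simulate_multiplex(40, 4, 1, 1, 0, seed = 2)
  G <- outer(pm$truth, 1:4, `==`) * 1
  ic <- build_icell(G, names(pm$truth), threshold_fraction = 0.25)
  same_cluster <- pm$truth[ic$edges[, 1]] == pm$truth[ic$edges[, 2]]
  expect_true(all(same_cluster))
  n <- 40
  expect_lte(n_edges(ic), n * ceiling(0.25 * (n - 1)))
})

test_that("hard clustering takes row argmax with deterministic tie-breaks", {
  G <- rbind(c(0.5, 0.5), c(0.1, 0.9), c(0, 0))
  expect_warning(cl <- hard_cluster(G, c("a", "b", "c")), "all-zero")
  expect_equal(unname(cl), c(1L, 2L, 1L))
  # brute-force argmax oracle on a random factor
  set.seed(11)
  G2 <- matrix(runif(80), 20, 4)
  cl2 <- hard_cluster(G2, sprintf("g%d", 1:20))
  expect_equal(unname(cl2), apply(G2, 1, which.max))
})

test_that("planted multi-layer clusters are recovered with high ARI", {
  skip_if_not_installed("mclust")
  pm <- simulate_multiplex(150, 3, 3, 0.3, 0.02, seed = 1)
  fit <- fuse(pm$multiplex, k = 3, max_iter = 300)
  expect_gte(ari(hard_cluster(fit), pm$truth), 0.9)
})
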