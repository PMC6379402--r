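#' Random initial factor
#'
#' Entries drawn i.i.d. uniform on (0, 1). Random starts make the solver
#' non-deterministic, which the stability analysis exploits to pick the
#' number of clusters.
#'
#' @param mx A `multiplex_networks`.
#' @param k Number of clusters.
#' @param seed Optional integer seed.
#' @return Non-negative n x k matrix with gene row names.
#' @export
init_random <- function(mx, k, seed = NULL) {
  n <- length(mx$gene_index)
  stopifnot(k >= 1, k <= n)
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(stats::runif(n * k), n, k)
  rownames(G) <- mx$gene_index
  G
}

#' SVD-based initial factor
#'
#' Deterministic initialization from the singular value decomposition of the
#' average adjacency matrix `A_bar = mean(A_i)`. Column `i` of the initial
#' factor is `sigma_i * g_i`, where `sigma_i` is the square root of the i-th
#' largest singular value and `g_i` is the non-negative part of the i-th left
#' singular vector with the larger norm (so the result is sign-invariant and
#' elementwise non-negative).
#'
#' @param mx A `multiplex_networks`.
#' @param k Number of clusters (columns); must not exceed n.
#' @return Non-negative n x k matrix. Columns beyond the numerical rank of
#'   `A_bar` are zero, with a warning.
#' @export
init_svd <- function(mx, k) {
  n <- length(mx$gene_index)
  stopifnot(k >= 1, k <= n)
  A_bar <- Reduce(`+`, mx$matrices) / length(mx$matrices)
  # A_bar is symmetric: its singular values are |eigenvalues| and the left
  # singular vectors are the eigenvectors; the symmetric eigendecomposition
  # is deterministic where a generic SVD may rotate degenerate pairs.
  es <- eigen(A_bar, symmetric = TRUE)
  ord <- order(abs(es$values), decreasing = TRUE)
  d <- abs(es$values)[ord]
  U <- es$vectors[, ord, drop = FALSE]
  G <- matrix(0, n, k)
  tol <- max(n, 1) * sqrt(.Machine$double.eps) * max(d, 1)
  n_zero <- 0L
  for (i in seq_len(k)) {
    if (d[i] <= tol) { n_zero <- n_zero + 1L; next }
    v <- U[, i]
    if (v[which.max(abs(v))] < 0) v <- -v   # canonical sign
    pos <- pmax(v, 0)
    neg <- pmax(-v, 0)
    g <- if (sqrt(sum(pos^2)) >= sqrt(sum(neg^2))) pos else neg
    G[, i] <- sqrt(d[i]) * g
  }
  if (n_zero > 0L) {
    warning("k exceeds numerical rank of the average adjacency; ",
            n_zero, " column(s) zero-padded")
  }
  rownames(G) <- mx$gene_index
  G
}

#' Closed-form update of a layer's compressed matrix
#'
#' With the shared factor fixed, each layer's k x k compressed matrix has the
#' closed form `S_i = (G'G)^-1 (G'A_iG) (G'G)^-1`. A ridge `epsilon` is
#' added to the Gram diagonal before inversion and the result is symmetrized
#' to remove floating-point drift.
#'
#' @param A_i Symmetric n x n adjacency matrix.
#' @param G Non-negative n x k factor.
#' @param epsilon Ridge added to the Gram diagonal (default 1e-10).
#' @return Symmetric k x k matrix.
#' @export
update_s <- function(A_i, G, epsilon = 1e-10) {
  if (nrow(A_i) != nrow(G) || ncol(A_i) != nrow(G)) stop("shape mismatch between A_i and G")
  gram <- crossprod(G)
  diag(gram) <- diag(gram) + epsilon
  gram_inv <- solve(gram)
  S <- gram_inv %*% (crossprod(G, A_i) %*% G) %*% gram_inv
  (S + t(S)) / 2
}

pos_part <- function(M) (abs(M) + M) / 2
neg_part <- function(M) (abs(M) - M) / 2

#' Multiplicative update of the shared factor
#'
#' One elementwise multiplicative step on the shared non-negative factor,
#' aggregating all layers. Matrices that may carry negative entries (the
#' compressed matrices) are split into positive and negative parts so that
#' numerator and denominator stay non-negative and the update preserves
#' `G >= 0`. Positions where both numerator and denominator vanish are left
#' unchanged; `epsilon` guards the denominator.
#'
#' @param mx A `multiplex_networks`.
#' @param S_list List of k x k compressed matrices, one per layer.
#' @param G Current non-negative factor.
#' @param epsilon Denominator guard (default 1e-10).
#' @param update_rule `"standard"` places the positive part of `A_i G S_i` in
#'   the numerator (the orientation that descends the objective);
#'   `"as_printed"` is the mirrored orientation.
#' @return Updated non-negative matrix of the same shape as `G`.
#' @export
update_g <- function(mx, S_list, G, epsilon = 1e-10,
                     update_rule = c("standard", "as_printed")) {
  update_rule <- match.arg(update_rule)
  num <- matrix(0, nrow(G), ncol(G))
  den <- matrix(0, nrow(G), ncol(G))
  gram <- crossprod(G)
  for (i in seq_along(S_list)) {
    S <- S_list[[i]]
    AGS <- mx$matrices[[i]] %*% G %*% S
    SGS <- S %*% gram %*% S
    num <- num + pos_part(AGS) + G %*% neg_part(SGS)
    den <- den + neg_part(AGS) + G %*% pos_part(SGS)
  }
  if (update_rule == "as_printed") { tmp <- num; num <- den; den <- tmp }
  ratio <- sqrt((num + epsilon) / (den + epsilon))
  ratio[num == 0 & den == 0] <- 1
  out <- G * ratio
  dimnames(out) <- dimnames(G)
  out
}

#' Relative square error of a factorization
#'
#' `RSE = sum_i ||A_i - G S_i G'||_F^2 / sum_i ||A_i||_F^2`: the Frobenius
#' residual of all layers normalized by the total input norm. 0 means an
#' exact factorization; the all-zero factorization scores 1.
#'
#' @param mx A `multiplex_networks`.
#' @param G n x k factor.
#' @param S_list List of k x k compressed matrices.
#' @return Non-negative fraction.
#' @export
rse <- function(mx, G, S_list) {
  denom <- sum(vapply(mx$matrices, function(A) sum(A^2), 0))
  if (denom == 0) stop("all layers are empty; RSE undefined")
  num <- 0
  for (i in seq_along(S_list)) {
    R <- mx$matrices[[i]] - G %*% S_list[[i]] %*% t(G)
    num <- num + sum(R^2)
  }
  num / denom
}

#' Fuse multiplex network layers by simultaneous symmetric NMTF
#'
#' Minimizes `sum_i ||A_i - G S_i G'||_F^2` over a shared non-negative n x k
#' factor `G` and per-layer symmetric k x k matrices `S_i` with a fixed-point
#' scheme: each iteration recomputes every `S_i` in closed form, then applies
#' one multiplicative update to `G`. The relative square error is recorded
#' each iteration.
#'
#' @param mx A `multiplex_networks`.
#' @param k Number of clusters (columns of `G`).
#' @param max_iter Iteration cap (default 1000).
#' @param epsilon Ridge/guard constant (default 1e-10).
#' @param init `"svd"` (deterministic), `"random"`, or an n x k non-negative
#'   matrix to start from.
#' @param seed Seed for random initialization.
#' @param update_rule See [update_g()].
#' @param early_stop If `TRUE`, stop when `|delta RSE| < 1e-9` for 10
#'   consecutive iterations (off by default: the fixed iteration cap is the
#'   reference behaviour).
#' @return An `icell_fusion` object: list with `G`, `S` (list of k x k
#'   matrices), `rse_trace`, `iterations`, `gene_index`, `config`.
#' @examples
#' pm <- simulate_multiplex(n = 30, k = 3, m = 2, p_in = 1, p_out = 0, seed = 1)
#' fit <- fuse(pm$multiplex, k = 3, max_iter = 50)
#' glance(fit)
#' @export
fuse <- function(mx, k, max_iter = 1000L, epsilon = 1e-10,
                 init = c("svd", "random"), seed = NULL,
                 update_rule = c("standard", "as_printed"),
                 early_stop = FALSE) {
  stopifnot(inherits(mx, "multiplex_networks"), max_iter >= 1L)
  update_rule <- match.arg(update_rule)
  n <- length(mx$gene_index)
  if (is.matrix(init)) {
    stopifnot(nrow(init) == n, ncol(init) == k, all(init >= 0))
    G <- init
    rownames(G) <- mx$gene_index
    init_method <- "custom"
  } else {
    init_method <- match.arg(init)
    G <- switch(init_method,
      svd = init_svd(mx, k),
      random = init_random(mx, k, seed = seed)
    )
  }
  rse_trace <- numeric(max_iter)
  stall <- 0L
  iter <- 0L
  S_list <- NULL
  for (it in seq_len(max_iter)) {
    S_list <- lapply(mx$matrices, update_s, G = G, epsilon = epsilon)
    G <- update_g(mx, S_list, G, epsilon = epsilon, update_rule = update_rule)
    if (!all(is.finite(G))) stop("non-finite values in G at iteration ", it)
    rse_trace[it] <- rse(mx, G, S_list)
    iter <- it
    if (early_stop && it > 1L) {
      stall <- if (abs(rse_trace[it] - rse_trace[it - 1L]) < 1e-9) stall + 1L else 0L
      if (stall >= 10L) break
    }
  }
  structure(
    list(
      G = G,
      S = S_list,
      rse_trace = rse_trace[seq_len(iter)],
      iterations = iter,
      gene_index = mx$gene_index,
      config = list(k = k, max_iter = max_iter, epsilon = epsilon,
                    init = init_method, seed = seed, update_rule = update_rule,
                    early_stop = early_stop, m = length(mx$matrices))
    ),
    class = "icell_fusion"
  )
}

#' @export
print.icell_fusion <- function(x, ...) {
  cat(sprintf(
    "<icell_fusion> n = %d genes, k = %d clusters, m = %d layers; %d iterations, final RSE %.4g\n",
    nrow(x$G), ncol(x$G), x$config$m, x$iterations,
    x$rse_trace[length(x$rse_trace)]
  ))
  invisible(x)
}

#' @export
tidy.icell_fusion <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$gene_index, ncol(x$G)),
    cluster = rep(seq_len(ncol(x$G)), each = nrow(x$G)),
    weight = as.vector(x$G)
  )
}

#' @export
glance.icell_fusion <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$G), k = ncol(x$G), m = x$config$m,
    iterations = x$iterations,
    rse = x$rse_trace[length(x$rse_trace)],
    init = x$config$init, update_rule = x$config$update_rule
  )
}

#' @export
autoplot.icell_fusion <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$rse_trace), rse = object$rse_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$rse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Relative square error") +
    ggplot2::theme_minimal()
}

#' Extract the integrated (iCell) network from a fused factor
#'
#' Forms `W = G G'` (zero diagonal) and keeps the strongest relationships:
#' pair `(u, v)` survives iff `W[u, v]` is among the top `ceiling(q * (n-1))`
#' positive entries of row `u` or of row `v` (the union keeps the result
#' symmetric; ties keep all tied values). The default `q = 0.01` keeps the
#' top 1% per row and column.
#'
#' @param fit An `icell_fusion` object, or an n x k non-negative matrix.
#' @param gene_index Gene identifiers (required when `fit` is a bare matrix).
#' @param threshold_fraction Fraction `q` in (0, 1] of each row to keep.
#' @return An `icell_network`: a [gene_network] on the full gene index with a
#'   `weights` element giving the retained `W` values per edge.
#' @export
build_icell <- function(fit, gene_index = NULL, threshold_fraction = 0.01) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  G <- if (inherits(fit, "icell_fusion")) fit$G else fit
  if (is.null(gene_index)) {
    gene_index <- if (inherits(fit, "icell_fusion")) fit$gene_index else rownames(G)
  }
  stopifnot(!is.null(gene_index), nrow(G) == length(gene_index))
  n <- nrow(G)
  W <- tcrossprod(G)
  diag(W) <- 0
  t_keep <- min(ceiling(threshold_fraction * (n - 1)), n - 1L)
  keep_row <- matrix(FALSE, n, n)
  for (u in seq_len(n)) {
    row <- W[u, ]
    thr <- sort(row, decreasing = TRUE)[t_keep]
    keep_row[u, ] <- row >= thr & row > 0
  }
  keep <- keep_row | t(keep_row)
  diag(keep) <- FALSE
  ij <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  net <- gene_network(gene_index,
                      cbind(gene_index[ij[, 1L]], gene_index[ij[, 2L]]),
                      layer_label = "icell")
  net$weights <- W[ij]
  attr(net, "threshold_fraction") <- threshold_fraction
  class(net) <- c("icell_network", class(net))
  net
}

#' @export
print.icell_network <- function(x, ...) {
  cat(sprintf("<icell_network> %d genes, %d retained edges (top %.3g%% per row/column)\n",
              n_nodes(x), n_edges(x), 100 * attr(x, "threshold_fraction")))
  invisible(x)
}

#' Hard clustering from the shared factor
#'
#' Assigns each gene to the cluster in which its factor row is largest
#' (`C(u) = argmax_i G[u, i]`); ties go to the lowest cluster index. An
#' all-zero row is assigned to cluster 1 with a warning.
#'
#' @param fit An `icell_fusion` object or an n x k matrix.
#' @param gene_index Gene identifiers (when `fit` is a bare matrix).
#' @return Named integer vector mapping gene to cluster in `1..k`.
#' @export
hard_cluster <- function(fit, gene_index = NULL) {
  G <- if (inherits(fit, "icell_fusion")) fit$G else fit
  if (is.null(gene_index)) {
    gene_index <- if (inherits(fit, "icell_fusion")) fit$gene_index else rownames(G)
  }
  stopifnot(ncol(G) >= 1L)
  zero_rows <- rowSums(G != 0) == 0L
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero row(s) assigned to cluster 1")
  }
  cl <- max.col(G, ties.method = "first")
  names(cl) <- gene_index
  cl
}
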