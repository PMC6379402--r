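#' Association matrix of a clustering
#'
#' `C[i, j] = 1` if genes i and j share a cluster, else 0; diagonal 1.
#' Averaging these over repeated runs gives the consensus matrix the
#' dispersion coefficients are computed from.
#'
#' @param clustering Named integer vector gene -> cluster.
#' @return Symmetric 0/1 matrix with unit diagonal and gene dimnames.
#' @export
association_matrix <- function(clustering) {
  C <- outer(clustering, clustering, `==`) * 1
  dimnames(C) <- list(names(clustering), names(clustering))
  C
}

#' Dispersion coefficients of an averaged association matrix
#'
#' Stability statistics of a consensus (averaged association) matrix
#' `C_bar` for `k` clusters over `n` genes:
#' `eta_k = var(offdiag(C_bar)) / (p - p^2)` with `p = (n/k - 1)/(n - 1)`
#' (population variance), and
#' `nu_k = sum_{i != j} (C_bar(i,j) - 1/k)^2 / (n (n-1) (1/k - 1/k^2))`.
#' For identical equal-size clusterings `eta_k = 1` exactly for every k,
#' while `nu_k = (n - k + 1)/(n - 1)` (exactly 1 only at k = 2); for
#' independent random clusterings both tend to 0.
#'
#' @param C_bar Averaged association matrix (entries in `[0, 1]`).
#' @param k Number of clusters the runs used.
#' @return Named numeric vector `c(eta = ..., nu = ...)`.
#' @export
dispersion_coefficients <- function(C_bar, k) {
  n <- nrow(C_bar)
  if (k < 2 || n <= k) stop("need n > k >= 2 for dispersion coefficients")
  off <- C_bar[row(C_bar) != col(C_bar)]
  p <- (n / k - 1) / (n - 1)
  eta_den <- p - p^2
  if (eta_den <= 0) stop("degenerate (n, k): eta denominator is zero")
  pop_var <- mean((off - mean(off))^2)
  eta <- pop_var / eta_den
  nu <- sum((off - 1 / k)^2) / (n * (n - 1) * (1 / k - 1 / k^2))
  c(eta = eta, nu = nu)
}

#' Select the number of clusters by clustering stability
#'
#' For each candidate `k`, runs the fusion solver `runs` times from random
#' initializations, hard-clusters each result, averages the association
#' matrices into a consensus matrix and computes the dispersion
#' coefficients. The chosen `k` maximizes `nu_k`, with ties broken by larger
#' `eta_k` and then by smaller `k`.
#'
#' @param mx A `multiplex_networks`.
#' @param k_grid Integer vector of candidate cluster counts.
#' @param runs Random-start runs per candidate (default 10).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param max_iter Solver iteration cap per run (default 1000).
#' @param ... Further arguments passed to [fuse()].
#' @return An `icell_stability` object: tibble with columns `k`, `eta`, `nu`
#'   plus attributes `chosen_k` and `runs`.
#' @export
select_k <- function(mx, k_grid, runs = 10L, seed = 1L, max_iter = 1000L, ...) {
  stopifnot(length(k_grid) >= 1L, runs >= 2L)
  n <- length(mx$gene_index)
  rows <- purrr::map(seq_along(k_grid), function(gi) {
    k <- k_grid[[gi]]
    C_sum <- matrix(0, n, n)
    for (r in seq_len(runs)) {
      run_seed <- (seed * 1000L + gi * 100L + r) %% .Machine$integer.max
      fit <- tryCatch(
        fuse(mx, k = k, max_iter = max_iter, init = "random",
             seed = run_seed, ...),
        error = function(e) stop("solver failed at k = ", k, ", run = ", r,
                                 ": ", conditionMessage(e))
      )
      C_sum <- C_sum + association_matrix(hard_cluster(fit))
    }
    dc <- dispersion_coefficients(C_sum / runs, k)
    tibble::tibble(k = k, eta = dc[["eta"]], nu = dc[["nu"]])
  })
  report <- dplyr::bind_rows(rows)
  ord <- order(-report$nu, -report$eta, report$k)
  structure(report,
            chosen_k = report$k[ord[1L]],
            runs = runs,
            class = c("icell_stability", class(report)))
}

#' @export
glance.icell_stability <- function(x, ...) {
  tibble::tibble(chosen_k = attr(x, "chosen_k"), runs = attr(x, "runs"),
                 k_min = min(x$k), k_max = max(x$k))
}

#' @export
autoplot.icell_stability <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("eta", "nu"),
                            names_to = "coefficient", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"), linetype = 2) +
    ggplot2::labs(x = "Number of clusters k", y = "Dispersion coefficient") +
    ggplot2::theme_minimal()
}
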