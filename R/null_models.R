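#' Random-graph null models
#'
#' Generates a simple undirected network from one of the seven literature
#' models commonly fitted to molecular networks:
#'
#' * `ER` — uniformly random edges; hits the target edge count
#'   `round(density * n(n-1)/2)` exactly.
#' * `ER-DD` — random edges constrained to a given degree sequence by stub
#'   matching (self-loops and multi-edges rejected, up to 100 restarts;
#'   residual unmatchable stubs are dropped with a message).
#' * `GEO` — n points uniform in the unit cube (`dim` dimensions, default 3),
#'   edges between pairs at Euclidean distance at most `r`; `r` is set to the
#'   order statistic of the pairwise distances that achieves the target edge
#'   count exactly.
#' * `GEO-GD` — geometric model with duplication-and-divergence placement:
#'   each new node is a copy of a random parent placed uniformly within a
#'   fixed dispersal step of it; edges then follow the GEO rule, with the
#'   connection radius calibrated to the target density via the distance
#'   order statistic (the dispersal process is scale-free, so only the
#'   step-to-radius ratio matters).
#' * `SF` — Barabasi-Albert preferential attachment ("rich-get-richer"),
#'   per-step attachment counts chosen so the total edge count matches the
#'   target.
#' * `SF-GD` — scale-free duplication and divergence: a duplicated node
#'   inherits its parent's neighbors, connects to the parent with probability
#'   `p`, and each shared neighbor loses one of its two connections with
#'   probability `q`; `q` is calibrated to the target density by bisection.
#' * `STICKY` — stickiness indices `theta_i` proportional to a given degree
#'   sequence (`theta_i = deg_i / sqrt(sum(deg))`); each pair connects
#'   independently with probability `min(1, theta_i * theta_j)`, so expected
#'   degrees match the input sequence.
#'
#' @param model One of `"ER"`, `"ER-DD"`, `"GEO"`, `"GEO-GD"`, `"SF"`,
#'   `"SF-GD"`, `"STICKY"`.
#' @param n Number of nodes.
#' @param density Target edge density in `(0, 1]` (all models except
#'   `ER-DD`/`STICKY`, which take a degree sequence).
#' @param degree_sequence Integer degree sequence (ER-DD, STICKY); must sum
#'   to an even number.
#' @param dim Dimension of the geometric space (GEO family; default 3).
#' @param p Parent-child connection probability for SF-GD (default 0.3).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A [gene_network] with nodes `v1 ... vn`.
#' @export
generate_model <- function(model = c("ER", "ER-DD", "GEO", "GEO-GD", "SF", "SF-GD", "STICKY"),
                           n, density = NULL, degree_sequence = NULL,
                           dim = 3L, p = 0.3, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("v", seq_len(n))
  edges <- switch(model,
    "ER" = {
      check_density(density)
      m <- round(density * n * (n - 1) / 2)
      g <- igraph::sample_gnm(n, m)
      igraph::as_edgelist(g, names = FALSE)
    },
    "ER-DD" = stub_matching_edges(degree_sequence, n),
    "GEO" = {
      check_density(density)
      geo_edges(stats::runif(n * dim), n, dim, round(density * n * (n - 1) / 2))
    },
    "GEO-GD" = geo_gd_edges(n, dim, density),
    "SF" = sf_edges(n, density),
    "SF-GD" = sf_gd_edges(n, density, p),
    "STICKY" = sticky_edges(degree_sequence, n)
  )
  if (NROW(edges) == 0L) {
    return(gene_network(nodes, NULL, layer_label = model))
  }
  gene_network(nodes, cbind(nodes[edges[, 1L]], nodes[edges[, 2L]]), layer_label = model)
}

check_density <- function(density) {
  if (is.null(density) || density <= 0 || density > 1) {
    stop("this model needs a target density in (0, 1]")
  }
}

check_degseq <- function(degree_sequence, n) {
  if (is.null(degree_sequence)) stop("this model needs a degree sequence")
  if (length(degree_sequence) != n) stop("degree sequence length must equal n")
  if (sum(degree_sequence) %% 2 != 0) stop("degree sequence must sum to an even number")
  if (any(degree_sequence < 0) || any(degree_sequence > n - 1)) {
    stop("unsatisfiable degree sequence")
  }
  invisible(TRUE)
}

# Stub matching with rejection: pair random stubs, reject self-loops and
# multi-edges, restart up to 100 times; drop whatever cannot be matched.
stub_matching_edges <- function(degree_sequence, n) {
  check_degseq(degree_sequence, n)
  stubs <- rep(seq_len(n), degree_sequence)
  best <- NULL
  for (attempt in seq_len(100L)) {
    perm <- stubs[sample.int(length(stubs))]
    a <- perm[seq(1L, length(perm), by = 2L)]
    b <- perm[seq(2L, length(perm), by = 2L)]
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- lo != hi & !duplicated(paste(lo, hi))
    cand <- cbind(lo[ok], hi[ok])
    if (is.null(best) || nrow(cand) > nrow(best)) best <- cand
    if (all(ok)) break
  }
  dropped <- length(stubs) / 2 - nrow(best)
  if (dropped > 0) {
    message("stub matching: dropped ", 2 * dropped, " unmatched stub(s)")
  }
  best
}

# Edges of a geometric graph: connect the m closest pairs (equivalently,
# radius = the m-th smallest pairwise distance).
geo_edges <- function(coords, n, dim, m) {
  geo_edges_from_points(matrix(coords, n, dim), m)
}

geo_edges_from_points <- function(pts, m) {
  d <- as.matrix(stats::dist(pts))
  if (m == 0L) return(matrix(integer(), ncol = 2L))
  r <- sort(d[upper.tri(d)], partial = m)[m]
  which(upper.tri(d) & d <= r, arr.ind = TRUE)
}

# Duplication-divergence placement followed by a geometric connection pass.
# The point process is scale-free in the dispersal step (rescaling the step
# rescales every pairwise distance by the same factor), so the resulting
# graph distribution depends only on the ratio of dispersal step to
# connection radius; the connection radius is therefore calibrated to the
# target edge count directly via the distance order statistic.
geo_gd_edges <- function(n, dim, density) {
  check_density(density)
  m <- round(density * n * (n - 1) / 2)
  pts <- matrix(0, n, dim)
  pts[2L, ] <- runif_ball(dim, 2)
  for (v in seq(3L, n)) {
    parent <- sample.int(v - 1L, 1L)
    pts[v, ] <- pts[parent, ] + runif_ball(dim, 2)
  }
  geo_edges_from_points(pts, m)
}

# Uniform point in a ball of given radius (rejection from the enclosing cube).
runif_ball <- function(dim, radius) {
  repeat {
    x <- stats::runif(dim, -radius, radius)
    if (sum(x^2) <= radius^2) return(x)
  }
}

sf_edges <- function(n, density) {
  check_density(density)
  m <- round(density * n * (n - 1) / 2)
  # distribute per-step attachment counts so the total hits m, capped by the
  # number of pre-existing nodes at each step
  cap <- pmin(seq_len(n) - 1L, n - 1L)
  outseq <- integer(n)
  remaining <- m
  base <- 0L
  while (remaining > 0L) {
    room <- which(outseq < cap)
    if (length(room) == 0L) break
    add <- utils::head(rev(room), remaining)   # later nodes have most capacity
    outseq[add] <- outseq[add] + 1L
    remaining <- remaining - length(add)
  }
  g <- igraph::sample_pa(n, out.seq = outseq, directed = FALSE, algorithm = "psumtree")
  igraph::as_edgelist(g, names = FALSE)
}

sf_gd_draw <- function(n, p, q) {
  adj <- vector("list", n)
  adj[[1L]] <- 2L; adj[[2L]] <- 1L
  for (u in seq(3L, n)) {
    v <- sample.int(u - 1L, 1L)
    nbrs <- adj[[v]]
    for (w in nbrs) adj[[w]] <- c(adj[[w]], u)
    adj[[u]] <- nbrs
    if (stats::runif(1) < p) {
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
    # divergence: each neighbor shared by parent and child may lose one link
    for (w in nbrs) {
      if (stats::runif(1) < q) {
        if (stats::runif(1) < 0.5) {
          adj[[u]] <- setdiff(adj[[u]], w); adj[[w]] <- setdiff(adj[[w]], u)
        } else {
          adj[[v]] <- setdiff(adj[[v]], w); adj[[w]] <- setdiff(adj[[w]], v)
        }
      }
    }
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- adj[[i]][adj[[i]] > i]
    if (length(js) == 0L) NULL else cbind(i, js)
  }))
  if (is.null(edges)) matrix(integer(), ncol = 2L) else edges
}

sf_gd_edges <- function(n, density, p, max_steps = 50L) {
  check_density(density)
  target <- density * n * (n - 1) / 2
  lo <- 0; hi <- 1
  for (step in seq_len(max_steps)) {
    q <- (lo + hi) / 2
    edges <- sf_gd_draw(n, p, q)
    m_hat <- nrow(edges)
    if (abs(m_hat - target) <= 0.05 * target) return(edges)
    if (m_hat > target) lo <- q else hi <- q
  }
  stop("SF-GD divergence-probability calibration did not converge after ",
       max_steps, " bisection steps")
}

sticky_edges <- function(degree_sequence, n) {
  check_degseq(degree_sequence, n)
  theta <- degree_sequence / sqrt(sum(degree_sequence))
  P <- outer(theta, theta)
  P[P > 1] <- 1
  up <- which(upper.tri(P))
  hit <- up[stats::runif(length(up)) < P[up]]
  if (length(hit) == 0L) return(matrix(integer(), ncol = 2L))
  cbind(row(P)[hit], col(P)[hit])
}

#' Fit random-graph models to a data network
#'
#' For each model, generates `reps` networks with the node count and edge
#' density (or degree sequence) of the data network, then compares the
#' distribution of GCD-11 distances between the data network and the model
#' networks against the distribution of GCD-11 distances among the model
#' networks. The two distributions are compared with a two-sided
#' Wilcoxon-Mann-Whitney test (normal approximation with tie correction);
#' the model is rejected as a fit when `p <= 0.05`. Lower mean data-to-model
#' distance indicates a better fit.
#'
#' @param real A [gene_network] with at least one edge.
#' @param models Character vector of model names (see [generate_model()]).
#' @param reps Replicate networks per model (default 30).
#' @param seed Master seed.
#' @param dim,p Passed to [generate_model()] for the GEO family and SF-GD.
#' @return An `icell_modelfit` object: tibble with one row per model
#'   (`model`, `mean_dist`, `sd_dist`, `mwu_p`, `rejected`) and a
#'   `distances` attribute holding the raw distance lists.
#' @export
fit_models <- function(real, models = c("ER", "ER-DD", "GEO", "GEO-GD", "SF", "SF-GD", "STICKY"),
                       reps = 30L, seed = 1L, dim = 3L, p = 0.3) {
  stopifnot(inherits(real, "gene_network"), reps >= 2L)
  if (n_edges(real) == 0L) stop("data network has no edges; model fitting undefined")
  n <- n_nodes(real)
  density <- n_edges(real) / (n * (n - 1) / 2)
  degseq <- node_degrees(real)
  if (sum(degseq) %% 2 != 0) stop("internal error: odd degree sum")
  gcm_real <- graphlet_correlation_matrix(real)
  up <- upper.tri(gcm_real)
  dists <- list()
  rows <- purrr::map(seq_along(models), function(mi) {
    model <- models[[mi]]
    gcms <- lapply(seq_len(reps), function(r) {
      net <- generate_model(model, n = n, density = density,
                            degree_sequence = degseq, dim = dim, p = p,
                            seed = (seed * 10000L + mi * 100L + r) %% .Machine$integer.max)
      graphlet_correlation_matrix(net)
    })
    real_to_model <- vapply(gcms, function(g) sqrt(sum((gcm_real[up] - g[up])^2)), 0)
    pairs <- utils::combn(reps, 2L)
    model_to_model <- vapply(seq_len(ncol(pairs)), function(j) {
      g1 <- gcms[[pairs[1L, j]]]; g2 <- gcms[[pairs[2L, j]]]
      sqrt(sum((g1[up] - g2[up])^2))
    }, 0)
    mwu <- stats::wilcox.test(real_to_model, model_to_model,
                              alternative = "two.sided", exact = FALSE, correct = TRUE)
    dists[[model]] <<- list(real_to_model = real_to_model, model_to_model = model_to_model)
    tibble::tibble(model = model,
                   mean_dist = mean(real_to_model), sd_dist = stats::sd(real_to_model),
                   mwu_p = mwu$p.value, rejected = mwu$p.value <= 0.05)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, distances = dists, reps = reps,
            class = c("icell_modelfit", class(out)))
}

#' Node degrees of a gene network
#'
#' @param net A [gene_network].
#' @return Named integer vector, in node order.
#' @export
node_degrees <- function(net) {
  deg <- integer(n_nodes(net))
  names(deg) <- net$nodes
  if (n_edges(net) > 0L) {
    t1 <- table(factor(net$edges[, 1L], levels = net$nodes))
    t2 <- table(factor(net$edges[, 2L], levels = net$nodes))
    deg <- as.integer(t1 + t2)
    names(deg) <- net$nodes
  }
  deg
}

#' @export
autoplot.icell_modelfit <- function(object, ...) {
  dists <- attr(object, "distances")
  df <- purrr::map_dfr(names(dists), function(m) {
    tibble::tibble(
      model = m,
      which = rep(c("data-to-model", "model-to-model"),
                  c(length(dists[[m]]$real_to_model), length(dists[[m]]$model_to_model))),
      distance = c(dists[[m]]$real_to_model, dists[[m]]$model_to_model)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$distance,
                                   fill = .data$which)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "GCD-11 distance", fill = NULL) +
    ggplot2::theme_minimal()
}
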