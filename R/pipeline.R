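#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Comma-separated
#' values become vectors. Recognized keys (defaults in parentheses):
#' `control_layers`, `case_layers` (comma-separated edge-list paths),
#' `layer_labels`, `expression` (binary expression table with columns
#' `control` and `case`), `annotations` (GMT), `markers` (gene list),
#' `background` (gene list; default: always-expressed genes), `out_dir`,
#' `k` (required), `max_iter` (1000), `epsilon` (1e-10), `init` (svd),
#' `threshold_fraction` (0.01), `alpha` (0.05), `top_n` (500), `seed` (1),
#' `node_policy` (union), `anchor` (optional layer label).
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",")[[1L]])
    cfg[[key]] <- val
  }
  cfg
}

cfg_get <- function(cfg, key, default = NULL, as = identity) {
  if (is.null(cfg[[key]])) default else as(cfg[[key]])
}

validate_run_config <- function(cfg) {
  for (key in c("control_layers", "case_layers")) {
    if (is.null(cfg[[key]])) stop("config missing required key: ", key)
  }
  if (is.null(cfg$k)) stop("config missing required key: k")
  if (is.null(cfg$out_dir)) stop("config missing required key: out_dir")
  paths <- c(cfg$control_layers, cfg$case_layers,
             cfg$expression, cfg$annotations, cfg$markers, cfg$background)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the integration pipeline end to end
#'
#' Executes the full analysis from one configuration: read the per-condition
#' layer edge lists, align each condition onto a shared gene index, fuse
#' each condition's layers, extract and write the integrated networks, hard
#' cluster, score per-gene rewiring between conditions over the
#' always-expressed genes, and (when annotation / marker files are given)
#' compute cluster enrichment and top-rewired marker enrichment. Every
#' output file is recorded in a manifest with its MD5 hash, so a rerun with
#' the same configuration reproduces an identical manifest.
#'
#' @param config Path to a configuration file (see [read_run_config()]) or
#'   an equivalent named list.
#' @return A manifest tibble (`file`, `md5`, `bytes`) with attributes
#'   `metrics` (named list of summary numbers) and `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  validate_run_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  labels <- cfg_get(cfg, "layer_labels", paste0("layer", seq_along(cfg$control_layers)))
  k <- cfg_get(cfg, "k", as = as.integer)
  max_iter <- cfg_get(cfg, "max_iter", 1000L, as.integer)
  epsilon <- cfg_get(cfg, "epsilon", 1e-10, as.numeric)
  init <- cfg_get(cfg, "init", "svd")
  q <- cfg_get(cfg, "threshold_fraction", 0.01, as.numeric)
  alpha <- cfg_get(cfg, "alpha", 0.05, as.numeric)
  top_n <- cfg_get(cfg, "top_n", 500L, as.integer)
  seed <- cfg_get(cfg, "seed", 1L, as.integer)
  node_policy <- cfg_get(cfg, "node_policy", "union")
  anchor <- cfg_get(cfg, "anchor")

  read_condition <- function(paths) {
    nets <- purrr::map2(paths, labels, read_edge_list)
    align_networks(nets, node_policy = node_policy, anchor = anchor)
  }
  log_stage <- function(fmt, ...) message(sprintf(paste0("[icellr] ", fmt), ...))

  log_stage("reading layers: %d control, %d case",
            length(cfg$control_layers), length(cfg$case_layers))
  mx_control <- read_condition(cfg$control_layers)
  mx_case <- read_condition(cfg$case_layers)
  shared <- intersect(mx_control$gene_index, mx_case$gene_index)

  log_stage("fusing (k = %d, max_iter = %d, init = %s)", k, max_iter, init)
  fit_control <- fuse(mx_control, k = k, max_iter = max_iter, epsilon = epsilon,
                      init = init, seed = seed)
  fit_case <- fuse(mx_case, k = k, max_iter = max_iter, epsilon = epsilon,
                   init = init, seed = seed + 1L)
  icell_control <- build_icell(fit_control, threshold_fraction = q)
  icell_case <- build_icell(fit_case, threshold_fraction = q)
  clustering_control <- hard_cluster(fit_control)
  clustering_case <- hard_cluster(fit_case)

  if (!is.null(cfg$expression)) {
    expr <- read_expression(cfg$expression)
    if (!all(c("control", "case") %in% names(expr))) {
      stop("expression table must have columns 'control' and 'case'")
    }
    parts <- partition_genes(intersect(expr$control, shared),
                             intersect(expr$case, shared), shared)
  } else {
    parts <- partition_genes(shared, shared, shared)
  }
  log_stage("scoring rewiring over %d always-expressed genes",
            length(parts$always_expressed))
  ranking <- rewiring_scores(icell_control, icell_case, parts$always_expressed)

  metrics <- list(
    n_control = length(mx_control$gene_index),
    n_case = length(mx_case$gene_index),
    rse_control = fit_control$rse_trace[fit_control$iterations],
    rse_case = fit_case$rse_trace[fit_case$iterations],
    icell_edges_control = n_edges(icell_control),
    icell_edges_case = n_edges(icell_case),
    n_always_expressed = length(parts$always_expressed)
  )

  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(
    write_edge_list(icell_control, file.path(out_dir, "icell_control.tsv")),
    write_edge_list(icell_case, file.path(out_dir, "icell_case.tsv")),
    write_tsv(data.frame(gene = names(clustering_control), cluster = clustering_control),
              "clusters_control.tsv"),
    write_tsv(data.frame(gene = names(clustering_case), cluster = clustering_case),
              "clusters_case.tsv"),
    write_tsv(as.data.frame(ranking), "rewiring_scores.tsv"),
    write_tsv(data.frame(iteration = seq_len(fit_control$iterations),
                         rse_control = fit_control$rse_trace,
                         rse_case = fit_case$rse_trace),
              "rse_trace.tsv")
  )

  if (!is.null(cfg$annotations)) {
    log_stage("cluster enrichment (alpha = %g)", alpha)
    ann <- read_gmt(cfg$annotations)
    enr <- cluster_enrichment(clustering_control, ann, alpha = alpha)
    metrics$percent_covered_control <- enr$percent_covered
    files <- c(files, write_tsv(as.data.frame(enr$table), "cluster_enrichment_control.tsv"))
  }
  if (!is.null(cfg$markers)) {
    markers <- read_gene_list(cfg$markers)
    background <- if (!is.null(cfg$background)) {
      read_gene_list(cfg$background)
    } else {
      parts$always_expressed
    }
    nn <- min(top_n, nrow(ranking))
    log_stage("marker enrichment in top %d rewired genes", nn)
    stats <- top_rewired_enrichment(ranking, top_n = nn,
                                    markers = markers, background = background)
    metrics$top_rewired_fold <- stats$fold
    metrics$top_rewired_p <- stats$p
    files <- c(files, write_tsv(as.data.frame(stats), "top_rewired_enrichment.tsv"))
  }

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
  write_tsv(as.data.frame(manifest), "manifest.tsv")
  structure(manifest, metrics = metrics, config = cfg, class = class(manifest))
}
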