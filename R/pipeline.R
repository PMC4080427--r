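#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults:
#' ternarization cutoff 0.35; EM controls (`max_iter` 100, `tol` 1e-6);
#' significance threshold `alpha` 0.05 and combined-label closeness `eps`
#' 0.05; permutation count `B` 999; miner `max_k` unbounded; k-means `k`
#' 50 when clustering is requested; master `seed` 1.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(cutoff = 0.35, max_iter = 100L, tol = 1e-6, alpha = 0.05, eps = 0.05,
       B = 999L, max_k = Inf, k = 50L, seed = 1L)
}

load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading a config file requires the 'yaml' package")
    }
    user <- yaml::read_yaml(path)
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  }
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

read_expression_auto <- function(path, tokens = ternary_tokens()) {
  probe <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                             colClasses = "character", check.names = FALSE,
                             nrows = 5L)
  if (all(trimws(as.matrix(probe)) %in% names(tokens))) {
    read_expression(path, dialect = "ternary", tokens = tokens)
  } else {
    read_expression(path, dialect = "real")
  }
}

#' Run the full inference pipeline
#'
#' Ternarize -> build modules -> infer individual TF roles -> mine
#' multi-TF collaborations, writing `singles.tsv`, `interactions.tsv`,
#' `modules.tsv` and the resolved `config.json` to `out_dir`.
#'
#' @param expression Expression table: a file path (TSV, real or ternary
#'   dialect auto-detected), a numeric matrix, or a [ternary_matrix()].
#' @param network Binding network: file path or [binding_network()].
#' @param clusters Cluster labels: file path, named vector, or `NULL`.
#'   When `NULL` and `kmeans = TRUE`, targets are clustered with
#'   [cluster_targets()]; when `NULL` otherwise, all genes form one
#'   cluster.
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing.
#' @param config Optional YAML config file path.
#' @param kmeans Cluster targets by expression when no labels are given.
#' @param ... Overrides for [default_config()] entries (`cutoff`, `alpha`,
#'   `eps`, `B`, `max_k`, `k`, `max_iter`, `tol`, `seed`).
#' @return Invisibly, list with `modules`, `singles`, `multi`, `fit`,
#'   `config`.
#' @export
run_infer <- function(expression, network, clusters = NULL, out_dir = NULL,
                      config = NULL, kmeans = FALSE, ...) {
  cfg <- load_config(config, list(...))
  expr <- if (is.character(expression)) read_expression_auto(expression) else expression
  if (!is_ternary_matrix(expr)) expr <- ternarize(expr, cutoff = cfg$cutoff)
  net <- if (is.character(network)) read_network(network) else network
  if (is.character(clusters)) clusters <- read_clusters(clusters)
  if (is.null(clusters) && isTRUE(kmeans)) {
    genes <- intersect(unique(net$gene), rownames(expr))
    clusters <- cluster_targets(expr, k = min(cfg$k, length(genes)),
                                seed = cfg$seed, genes = genes)
  }
  modules <- build_modules(net, clusters)
  if (!length(modules)) {
    warning("no regulatory modules could be built; outputs are empty")
    singles <- data.frame(module_id = character(), tf_id = character(),
                          label = character(), posterior = numeric(),
                          p_value = numeric(), stringsAsFactors = FALSE)
    multi <- mine_interactions(structure(list(), class = "regulatory_modules"), expr)
    fit <- NULL
  } else {
    ind <- infer_individual(modules, expr, alpha = cfg$alpha, eps = cfg$eps,
                            B = cfg$B, max_iter = cfg$max_iter, tol = cfg$tol,
                            seed = cfg$seed)
    singles <- ind$results
    fit <- ind$fit
    multi <- mine_interactions(modules, expr, singles = singles,
                               alpha = cfg$alpha, max_k = cfg$max_k)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_modules(modules, file.path(out_dir, "modules.tsv"))
    write_tsv(singles, file.path(out_dir, "singles.tsv"))
    write_tsv(multi, file.path(out_dir, "interactions.tsv"))
    cfg_out <- cfg
    cfg_out$max_k <- if (is.finite(cfg$max_k)) cfg$max_k else "unbounded"
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(modules = modules, singles = singles, multi = multi,
                 fit = fit, config = cfg))
}

#' Simulate a synthetic benchmark dataset to disk
#'
#' Writes `network.tsv` (two-column edge list), `expression.tsv` (ternary
#' tokens), `truth_rules.tsv` (planted interactions) and
#' `truth_edges.tsv` (tf, gene, decoy flag) to `out_dir`.
#'
#' @param out_dir Output directory.
#' @param params Generator parameters ([figure_defaults()]).
#' @param noise_rate Cell corruption probability.
#' @param seed Integer seed.
#' @return Invisibly, the [simulate_trn()] result.
#' @export
run_simulate <- function(out_dir, params = figure_defaults(), noise_rate = 0.1,
                         seed = 1L) {
  sim <- simulate_trn(params = params, noise_rate = noise_rate, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_network(sim$truth$network, file.path(out_dir, "network.tsv"))
  write_expression(sim$expr, file.path(out_dir, "expression.tsv"))
  write_truth(sim$truth, file.path(out_dir, "truth_rules.tsv"))
  edges <- cbind(sim$truth$network, decoy = sim$truth$decoy)
  write_tsv(edges, file.path(out_dir, "truth_edges.tsv"))
  invisible(sim)
}

#' Evaluate predictions against a synthetic ground truth
#'
#' Edge-mode confusion counts and precision/recall/specificity, written as
#' JSON (and returned).
#'
#' @param result A [run_infer()] result, or a directory containing
#'   `singles.tsv`, `interactions.tsv`, `modules.tsv`.
#' @param truth A `synthetic_truth`, or a directory containing
#'   `truth_edges.tsv` (+ `truth_rules.tsv`).
#' @param out Optional JSON report path.
#' @return List with `counts` ([confusion_counts()]) and the metrics.
#' @export
run_evaluate <- function(result, truth, out = NULL) {
  if (is.character(result)) {
    singles <- utils::read.table(file.path(result, "singles.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
    multi <- utils::read.table(file.path(result, "interactions.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    mdf <- utils::read.table(file.path(result, "modules.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    modules <- structure(lapply(seq_len(nrow(mdf)), function(i) {
      list(module_id = mdf$module_id[i],
           tfs = strsplit(mdf$tfs[i], ";", fixed = TRUE)[[1L]],
           genes = strsplit(mdf$genes[i], ";", fixed = TRUE)[[1L]],
           cluster = mdf$cluster[i])
    }), class = "regulatory_modules")
  } else {
    singles <- result$singles; multi <- result$multi; modules <- result$modules
  }
  if (is.character(truth)) {
    edges <- utils::read.table(file.path(truth, "truth_edges.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    rules_path <- file.path(truth, "truth_rules.tsv")
    rules <- if (file.exists(rules_path)) {
      utils::read.table(rules_path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    }
    truth <- structure(list(network = binding_network(edges$tf, edges$gene),
                            decoy = edges$decoy, rules = rules),
                       class = "synthetic_truth")
  }
  counts <- match_predictions(singles, multi, truth, modules, mode = "edge")
  metrics <- prf_metrics(counts)
  report <- c(list(tp = counts$tp, fp = counts$fp, tn = counts$tn,
                   fn = counts$fn), metrics)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  list(counts = counts, precision = metrics$precision, recall = metrics$recall,
       specificity = metrics$specificity)
}
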