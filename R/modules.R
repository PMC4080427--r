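#' Cluster target genes by expression profile
#'
#' k-means under the (1 - Pearson correlation) distance: each profile is
#' centered and scaled to unit variance, after which squared Euclidean
#' distance is proportional to correlation distance, and [stats::kmeans()]
#' is run on the standardized profiles. Ternary matrices are clustered on
#' their -1/0/+1 coding. Constant (zero-variance) profiles are mapped to
#' the zero profile.
#'
#' @param expr Numeric matrix or [ternary_matrix()] with one row per gene.
#' @param k Number of clusters (>= 1, <= number of genes).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param genes Optional character vector restricting clustering to a gene
#'   subset (default: all rows).
#' @return Named character vector gene -> cluster id (`"1"`..`"k"`).
#' @export
cluster_targets <- function(expr, k, seed = 1L, genes = rownames(expr)) {
  missing_rows <- setdiff(genes, rownames(expr))
  if (length(missing_rows)) {
    stop_input("no expression profile for gene '%s'", missing_rows[1L])
  }
  x <- unclass(expr)[genes, , drop = FALSE]
  storage.mode(x) <- "double"
  if (k < 1L) stop_input("k must be >= 1")
  if (k > nrow(x)) stop_infeasible("k = %d exceeds the number of genes (%d)", k, nrow(x))
  if (k == nrow(x)) {
    return(stats::setNames(as.character(seq_len(nrow(x))), rownames(x)))
  }
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0
  if (k == 1L) return(stats::setNames(rep("1", nrow(x)), rownames(x)))
  fit <- with_seed(seed, stats::kmeans(z, centers = k, nstart = 10L, iter.max = 100L))
  stats::setNames(as.character(fit$cluster), rownames(x))
}

#' Build regulatory modules from a binding network and cluster labels
#'
#' Target genes are grouped by the exact set of TFs that bind them; groups
#' are then partitioned by cluster label, so every module's genes share
#' both the identical bound-TF set and the same co-expression cluster.
#' Genes without a cluster label are dropped with a warning. Module TFs
#' are sorted lexicographically (the global TF order used throughout the
#' miner), and module ids are assigned deterministically from the sorted
#' (TF set, cluster) keys, independent of the input edge order.
#'
#' @param net `binding_network` (see [binding_network()]).
#' @param clusters Named vector gene -> cluster id, or `NULL` to treat all
#'   genes as one cluster.
#' @return List of modules of class `regulatory_modules`; each module is a
#'   list with `module_id`, `tfs` (sorted), `genes`, `cluster`.
#' @export
build_modules <- function(net, clusters = NULL) {
  if (!nrow(net)) return(structure(list(), class = "regulatory_modules"))
  genes <- unique(net$gene)
  if (is.null(clusters)) clusters <- stats::setNames(rep("1", length(genes)), genes)
  unlabeled <- setdiff(genes, names(clusters))
  if (length(unlabeled)) {
    warning(sprintf("%d bound gene(s) without cluster label dropped from modules",
                    length(unlabeled)))
    genes <- setdiff(genes, unlabeled)
  }
  tf_sets <- lapply(split(net$tf, net$gene), function(s) sort(unique(s)))
  keys <- vapply(genes, function(g) {
    paste(paste(tf_sets[[g]], collapse = ";"), clusters[[g]], sep = "|")
  }, "")
  groups <- split(genes, keys)
  groups <- groups[order(names(groups))]
  modules <- lapply(seq_along(groups), function(i) {
    gs <- sort(groups[[i]])
    list(module_id = sprintf("M%03d", i),
         tfs = tf_sets[[gs[1L]]],
         genes = gs,
         cluster = unname(clusters[[gs[1L]]]))
  })
  message(sprintf("built %d regulatory module(s) over %d gene(s); TF-set sizes: %s",
                  length(modules), length(genes),
                  paste(range(vapply(modules, function(m) length(m$tfs), 0L)),
                        collapse = "-")))
  structure(modules, class = "regulatory_modules")
}

#' @export
as.data.frame.regulatory_modules <- function(x, ...) {
  data.frame(
    module_id = vapply(x, `[[`, "", "module_id"),
    tfs = vapply(x, function(m) paste(m$tfs, collapse = ";"), ""),
    genes = vapply(x, function(m) paste(m$genes, collapse = ";"), ""),
    cluster = vapply(x, function(m) as.character(m$cluster), ""),
    stringsAsFactors = FALSE
  )
}

#' @export
print.regulatory_modules <- function(x, ...) {
  cat(sprintf("%d regulatory module(s)\n", length(x)))
  if (length(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}
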