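#' Confusion counts
#'
#' @param tp,fp,tn,fn Nonnegative integer counts over a fixed prediction
#'   universe.
#' @return List of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

# edges (tf -> gene) implied by reported interactions
predictions_to_edges <- function(singles, multi, modules) {
  module_by_id <- stats::setNames(modules, vapply(modules, `[[`, "", "module_id"))
  edges <- list()
  add <- function(tf, genes) {
    edges[[length(edges) + 1L]] <<- data.frame(tf = tf, gene = genes,
                                               stringsAsFactors = FALSE)
  }
  if (!is.null(singles) && nrow(singles)) {
    hit <- singles$label != "NoDecision"
    for (i in which(hit)) {
      add(singles$tf_id[i], module_by_id[[singles$module_id[i]]]$genes)
    }
  }
  if (!is.null(multi) && nrow(multi)) {
    for (i in seq_len(nrow(multi))) {
      tf_ids <- vapply(strsplit(strsplit(multi$tf_states[i], ";", fixed = TRUE)[[1L]],
                                ":", fixed = TRUE), `[[`, "", 1L)
      for (tf in tf_ids) add(tf, module_by_id[[multi$module_id[i]]]$genes)
    }
  }
  if (!length(edges)) {
    return(data.frame(tf = character(), gene = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, edges))
}

#' Score predictions against a synthetic ground truth
#'
#' In `edge` mode the universe is the synthetic network's edge set: an
#' edge is predicted positive when it participates in any reported
#' interaction (individual or multi-TF) and truly positive when it is a
#' regulatory (non-decoy) edge. In `interaction` mode predictions are
#' matched exactly against planted rules on (TF set, states, target
#' direction) — for single-TF rules, on the role label — and the universe
#' is the union of planted and predicted interactions (so `tn = 0`).
#'
#' @param singles Stage-1 results data frame (or `NULL`).
#' @param multi Stage-2 results data frame (or `NULL`).
#' @param truth `synthetic_truth` with planted rules.
#' @param modules `regulatory_modules` used for the predictions.
#' @param mode `"edge"` or `"interaction"`.
#' @return [confusion_counts()].
#' @export
match_predictions <- function(singles, multi, truth, modules,
                              mode = c("edge", "interaction")) {
  mode <- match.arg(mode)
  if (mode == "edge") {
    pred <- predictions_to_edges(singles, multi, modules)
    net_keys <- paste(truth$network$tf, truth$network$gene)
    pred_keys <- paste(pred$tf, pred$gene)
    unknown <- setdiff(pred_keys, net_keys)
    if (length(unknown)) stop_input("predicted edge outside the network: %s", unknown[1L])
    predicted <- net_keys %in% pred_keys
    positive <- !truth$decoy
    return(confusion_counts(
      tp = sum(predicted & positive), fp = sum(predicted & !positive),
      tn = sum(!predicted & !positive), fn = sum(!predicted & positive)
    ))
  }
  truth_keys <- apply(truth$rules, 1L, function(r) {
    if (r[["k"]] == "1" || r[["k"]] == 1) {
      paste0(r[["target"]], "|1|", r[["tfs"]], "|", r[["label"]])
    } else {
      paste0(r[["target"]], "|k|", r[["tfs"]], "|", r[["states"]], "|", r[["g_state"]])
    }
  })
  module_by_id <- stats::setNames(modules, vapply(modules, `[[`, "", "module_id"))
  pred_keys <- character()
  if (!is.null(singles) && nrow(singles)) {
    hit <- singles$label != "NoDecision"
    for (i in which(hit)) {
      for (g in module_by_id[[singles$module_id[i]]]$genes) {
        pred_keys <- c(pred_keys,
                       paste0(g, "|1|", singles$tf_id[i], "|", singles$label[i]))
      }
    }
  }
  if (!is.null(multi) && nrow(multi)) {
    for (i in seq_len(nrow(multi))) {
      parts <- strsplit(strsplit(multi$tf_states[i], ";", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
      tf_ids <- vapply(parts, `[[`, "", 1L)
      sts <- vapply(parts, `[[`, "", 2L)
      for (g in module_by_id[[multi$module_id[i]]]$genes) {
        pred_keys <- c(pred_keys,
                       paste0(g, "|k|", paste(tf_ids, collapse = ";"), "|",
                              paste(sts, collapse = ";"), "|", multi$g_state[i]))
      }
    }
  }
  pred_keys <- unique(pred_keys)
  confusion_counts(
    tp = sum(pred_keys %in% truth_keys),
    fp = sum(!(pred_keys %in% truth_keys)),
    tn = 0L,
    fn = sum(!(truth_keys %in% pred_keys))
  )
}

#' Precision, recall and specificity from confusion counts
#'
#' A metric whose denominator is zero is returned as `NA` (flagged null)
#' rather than `NaN`.
#'
#' @param c [confusion_counts()].
#' @return Named list: `precision`, `recall`, `specificity`.
#' @export
prf_metrics <- function(c) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision = ratio(c$tp, c$tp + c$fp),
       recall = ratio(c$tp, c$tp + c$fn),
       specificity = ratio(c$tn, c$tn + c$fp))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation with midranks for ties: the probability that
#' a random positive item outranks a random negative one.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) vector of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_input("roc_auc needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
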