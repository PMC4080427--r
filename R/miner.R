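#' Probability of a ternary expression pattern
#'
#' The probability of a pattern is the number of (time point, gene) pairs
#' at which every constraint holds, divided by the number of time points
#' times the number of target genes. TF constraints are gene-independent
#' (a matching time point counts once per gene); the optional target
#' direction constraint is evaluated per gene.
#'
#' @param expr [ternary_matrix()].
#' @param genes Character vector of the module's target genes (non-empty).
#' @param tf_states Named integer vector of TF constraints
#'   (`c(tf1 = 1, tf3 = -1)` for tf1-up and tf3-down), or `NULL`.
#' @param g_state Target direction (`1` or `-1`), or `NULL`.
#' @return Probability in \[0, 1\].
#' @export
pattern_probability <- function(expr, genes, tf_states = NULL, g_state = NULL) {
  if (!length(genes)) stop_input("pattern_probability requires a non-empty gene set")
  if (!length(tf_states) && is.null(g_state)) {
    stop_input("empty pattern: give at least one TF constraint or a target direction")
  }
  x <- unclass(expr)
  missing_rows <- setdiff(c(names(tf_states), genes), rownames(x))
  if (length(missing_rows)) stop_input("no expression row for '%s'", missing_rows[1L])
  T <- ncol(x)
  ind <- rep(TRUE, T)
  for (i in seq_along(tf_states)) {
    ind <- ind & (x[names(tf_states)[i], ] == tf_states[[i]])
  }
  if (is.null(g_state)) {
    count <- sum(ind) * length(genes)
  } else {
    cnt_g <- colSums(x[genes, , drop = FALSE] == g_state)
    count <- sum(cnt_g[ind])
  }
  count / (T * length(genes))
}

#' Affinity score of a candidate multi-TF interaction
#'
#' For a candidate `<h_tf1, ..., h_tfk> => h_g`, the score is
#' `P(pattern and target) * P(target) / P(pattern)`, with pattern
#' probabilities as in [pattern_probability()]. Algebraically this equals
#' `P(target | pattern) * P(target)`, so the score lies in \[0, 1\] and
#' never exceeds `P(target)`. Returns 0 when the TF pattern never occurs.
#'
#' @inheritParams pattern_probability
#' @param tf_states Named integer vector of TF constraints (states must
#'   be up/down, never no-change).
#' @param g_state Target direction, `1` or `-1`.
#' @return Score in \[0, 1\].
#' @export
afn_score <- function(expr, genes, tf_states, g_state) {
  if (!length(tf_states)) stop_input("afn_score requires at least one TF constraint")
  if (anyDuplicated(names(tf_states))) stop_input("repeated TF in candidate")
  if (!all(tf_states %in% c(-1L, 1L)) || !g_state %in% c(-1L, 1L)) {
    stop_input("candidate states must be up (1) or down (-1)")
  }
  p_tf <- pattern_probability(expr, genes, tf_states = tf_states)
  if (p_tf == 0) return(0)
  p_joint <- pattern_probability(expr, genes, tf_states = tf_states, g_state = g_state)
  p_g <- pattern_probability(expr, genes, g_state = g_state)
  p_joint * p_g / p_tf
}

#' Size of the multi-TF candidate space of a module
#'
#' Number of possible k-TF interactions for k = 2..m with each TF
#' constrained up or down and the target direction up or down:
#' `sum_k C(m, k) * 2^k * 2`. A module with three TFs has 40.
#'
#' @param m Number of TFs in the module.
#' @return Integer count (0 for m < 2).
#' @export
count_candidate_space <- function(m) {
  if (m < 2) return(0L)
  k <- 2:m
  as.integer(sum(choose(m, k) * 2^k * 2))
}

#' Enumerate all k-TF candidates over a TF set
#'
#' Every combination of k TFs, every up/down state assignment and both
#' target directions, in deterministic order.
#'
#' @param tfs Character vector of TF ids (sorted).
#' @param k Number of TFs per candidate.
#' @return List of candidates, each `list(tfs, states, dir)`.
#' @export
enumerate_candidates <- function(tfs, k) {
  if (k < 1L || k > length(tfs)) return(list())
  combos <- utils::combn(sort(tfs), k, simplify = FALSE)
  states_grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), k)))
  out <- list()
  for (cb in combos) {
    for (r in seq_len(nrow(states_grid))) {
      for (d in c(1L, -1L)) {
        out[[length(out) + 1L]] <- list(tfs = cb,
                                        states = unname(states_grid[r, ]),
                                        dir = d)
      }
    }
  }
  out
}

# Canonical key of a candidate: O(k) to build, used by the hash index.
candidate_key <- function(tfs, states, dir) {
  paste0(dir, "|", paste(tfs, states, sep = ":", collapse = ";"))
}

#' Candidate index
#'
#' Hash-backed store of interaction patterns keyed by the sorted
#' (TF, state) sequence plus target direction; insertion and lookup build
#' one O(k) key and touch a single hash node.
#'
#' @return An index object (environment).
#' @export
candidate_index <- function() {
  new.env(parent = emptyenv(), hash = TRUE)
}

#' @rdname candidate_index
#' @param index Index created by [candidate_index()].
#' @param tfs,states,dir Candidate fields (TFs sorted).
#' @export
index_insert <- function(index, tfs, states, dir) {
  assign(candidate_key(tfs, states, dir), TRUE, envir = index)
  invisible(index)
}

#' @rdname candidate_index
#' @export
index_contains <- function(index, tfs, states, dir) {
  exists(candidate_key(tfs, states, dir), envir = index, inherits = FALSE)
}

#' Merge two (k-1)-TF candidates into a k-TF candidate
#'
#' Candidates are combinable when they predict the same target direction
#' and their sorted constraint vectors differ in exactly one TF identity
#' (so they share k-2 identical (TF, state) pairs); the merge is the
#' k-constraint union, re-sorted. Returns `NULL` when not combinable,
#' including when the same TF would be constrained to two states.
#'
#' @param i1,i2 Candidates (`list(tfs, states, dir)`, TFs sorted).
#' @return Merged candidate or `NULL`.
#' @export
combine_candidates <- function(i1, i2) {
  if (is.unsorted(i1$tfs) || is.unsorted(i2$tfs)) {
    stop_input("candidates must have TFs in sorted order")
  }
  if (i1$dir != i2$dir || length(i1$tfs) != length(i2$tfs)) return(NULL)
  k <- length(i1$tfs) + 1L
  tfs <- c(i1$tfs, i2$tfs)
  states <- c(i1$states, i2$states)
  ord <- order(tfs, method = "radix")
  tfs <- tfs[ord]; states <- states[ord]
  dup <- duplicated(tfs)
  u_tfs <- tfs[!dup]; u_states <- states[!dup]
  if (length(u_tfs) != k) return(NULL)          # shares fewer than k-2 TFs
  # a TF present in both candidates must carry the same state in both
  for (tf in tfs[dup]) {
    if (length(unique(states[tfs == tf])) != 1L) return(NULL)
  }
  list(tfs = u_tfs, states = u_states, dir = i1$dir)
}

#' Should a candidate be pruned because a one-smaller subset is significant?
#'
#' Checks the k patterns obtained by deleting one TF constraint against
#' the index of already-significant interactions; each lookup costs O(k).
#'
#' @param cand Candidate (`list(tfs, states, dir)`).
#' @param significant_index [candidate_index()] of significant patterns.
#' @return `TRUE` to prune.
#' @export
prune_by_subset <- function(cand, significant_index) {
  k <- length(cand$tfs)
  for (j in seq_len(k)) {
    if (index_contains(significant_index, cand$tfs[-j], cand$states[-j], cand$dir)) {
      return(TRUE)
    }
  }
  FALSE
}

# Any proper subpattern (any size >= 1, same direction) in the index?
has_significant_subpattern <- function(cand, significant_index) {
  k <- length(cand$tfs)
  for (size in seq_len(k - 1L)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      if (index_contains(significant_index, cand$tfs[idx], cand$states[idx], cand$dir)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Level-wise p-values for affinity scores
#'
#' Each score is tested one-sided (upper tail) against the distribution of
#' same-level scores: a location-scale t model is fit to the remaining
#' scores (leave-one-out mean and standard deviation, df = n - 2) and the
#' p-value is the survival probability of the candidate's score. With
#' fewer than three null scores, or zero variance among them, all
#' p-values are 1 (with a warning).
#'
#' @param scores Numeric vector of candidate scores.
#' @param null_scores Scores forming the level's null distribution;
#'   defaults to `scores` itself. A candidate's own score is removed once
#'   from the null before fitting.
#' @return p-values in (0, 1], one per element of `scores`.
#' @export
level_pvalues <- function(scores, null_scores = scores) {
  n_eff <- length(null_scores)
  if (n_eff < 3L) {
    if (length(scores)) warning("fewer than 3 scores at this level; p-values set to 1")
    return(rep(1, length(scores)))
  }
  vapply(scores, function(x) {
    i <- match(x, null_scores)
    loo <- if (is.na(i)) null_scores else null_scores[-i]
    s <- stats::sd(loo)
    if (!is.finite(s) || s == 0) return(1)
    p <- stats::pt((x - mean(loo)) / s, df = length(loo) - 1L, lower.tail = FALSE)
    min(max(p, .Machine$double.xmin), 1)
  }, 0)
}

# Map a stage-1 label to the 1-TF pattern(s) it asserts.
label_patterns <- function(label) {
  base <- list(
    AN = list(list(s = -1L, d = -1L)), AS = list(list(s = 1L, d = 1L)),
    RN = list(list(s = -1L, d = 1L)), RS = list(list(s = 1L, d = -1L)),
    ANS = list(list(s = -1L, d = -1L), list(s = 1L, d = 1L)),
    RNS = list(list(s = -1L, d = 1L), list(s = 1L, d = -1L))
  )
  base[[label]] %||% list()
}

# Fast per-module affinity scorer; precomputes indicator rows.
module_scorer <- function(expr, tfs, genes) {
  x <- unclass(expr)
  T <- ncol(x)
  n_g <- length(genes)
  up <- x[tfs, , drop = FALSE] == 1L
  down <- x[tfs, , drop = FALSE] == -1L
  cnt <- list(`1` = colSums(x[genes, , drop = FALSE] == 1L),
              `-1` = colSums(x[genes, , drop = FALSE] == -1L))
  g_tot <- c(`1` = sum(cnt$`1`), `-1` = sum(cnt$`-1`))
  N <- T * n_g
  function(cand_tfs, states, dir) {
    ind <- rep(TRUE, T)
    for (i in seq_along(cand_tfs)) {
      ind <- ind & (if (states[i] == 1L) up[cand_tfs[i], ] else down[cand_tfs[i], ])
    }
    p_tf <- sum(ind) * n_g
    if (p_tf == 0) return(0)
    joint <- sum(cnt[[as.character(dir)]][ind])
    (joint / N) * (g_tot[[as.character(dir)]] / N) / (p_tf / N)
  }
}

#' Mine minimal significant multi-TF interactions in one module
#'
#' Bottom-up level-wise search. Level 1 is seeded with every 1-TF pattern
#' (TF up/down, target direction up/down) that occurs at least once in the
#' data and is not already a significant individual-role pattern from
#' stage 1; the stage-1 significant patterns seed the significance index.
#' At level k, pairs of insignificant (k-1)-TF candidates that predict the
#' same target direction and differ in exactly one TF identity are merged
#' ([combine_candidates()]); merged candidates with a significant
#' subpattern are pruned; the rest are scored with [afn_score()] and
#' tested against the distribution of affinity scores of *all* possible
#' k-TF interactions of the module ([level_pvalues()] with the full
#' enumeration as the null). Significant candidates (p < `alpha`) are
#' reported and indexed; insignificant ones are carried to the next level.
#' The output is minimal: no reported interaction has a significant proper
#' subpattern.
#'
#' @param module One regulatory module (list with `module_id`, `tfs`,
#'   `genes`).
#' @param expr [ternary_matrix()].
#' @param singles Stage-1 results data frame (module_id, tf_id, label) or
#'   `NULL` (treat all TFs as undecided).
#' @param alpha Significance threshold.
#' @param max_k Largest interaction size to mine (default: module size).
#' @return Data frame: module_id, k, tf_states (e.g. `"tf1:up;tf3:down"`),
#'   g_state, afn_score, p_value, logic (`sufficient` when all TF states
#'   are up, `necessary` when all down, else `mixed`).
#' @export
mine_module <- function(module, expr, singles = NULL, alpha = 0.05, max_k = Inf) {
  tfs <- sort(module$tfs)
  m <- length(tfs)
  empty <- data.frame(module_id = character(), k = integer(),
                      tf_states = character(), g_state = character(),
                      afn_score = numeric(), p_value = numeric(),
                      logic = character(), stringsAsFactors = FALSE)
  if (m < 2L) return(empty)
  score_fun <- module_scorer(expr, tfs, module$genes)

  sig_index <- candidate_index()
  if (!is.null(singles) && nrow(singles)) {
    here <- singles[singles$module_id == module$module_id &
                      singles$label != "NoDecision", , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      for (pat in label_patterns(here$label[i])) {
        index_insert(sig_index, here$tf_id[i], pat$s, pat$d)
      }
    }
  }

  P <- list()
  for (tf in tfs) {
    for (s in c(1L, -1L)) {
      for (d in c(1L, -1L)) {
        if (index_contains(sig_index, tf, s, d)) next
        joint <- pattern_probability(expr, module$genes,
                                     tf_states = stats::setNames(s, tf),
                                     g_state = d)
        if (joint > 0) P[[length(P) + 1L]] <- list(tfs = tf, states = s, dir = d)
      }
    }
  }

  results <- list()
  k <- 2L
  while (length(P) >= 2L && k <= min(m, max_k)) {
    seen <- candidate_index()
    gen <- list()
    for (a in seq_len(length(P) - 1L)) {
      for (b in (a + 1L):length(P)) {
        cand <- combine_candidates(P[[a]], P[[b]])
        if (is.null(cand)) next
        if (index_contains(seen, cand$tfs, cand$states, cand$dir)) next
        index_insert(seen, cand$tfs, cand$states, cand$dir)
        if (has_significant_subpattern(cand, sig_index)) next
        gen[[length(gen) + 1L]] <- cand
      }
    }
    if (!length(gen)) break
    pop <- vapply(enumerate_candidates(tfs, k),
                  function(c) score_fun(c$tfs, c$states, c$dir), 0)
    scores <- vapply(gen, function(c) score_fun(c$tfs, c$states, c$dir), 0)
    pvals <- level_pvalues(scores, null_scores = pop)
    sig <- pvals < alpha
    for (i in which(sig)) {
      cand <- gen[[i]]
      index_insert(sig_index, cand$tfs, cand$states, cand$dir)
      results[[length(results) + 1L]] <- data.frame(
        module_id = module$module_id, k = k,
        tf_states = paste(cand$tfs, state_to_word(cand$states),
                          sep = ":", collapse = ";"),
        g_state = state_to_word(cand$dir),
        afn_score = scores[i], p_value = pvals[i],
        logic = if (all(cand$states == 1L)) "sufficient"
                else if (all(cand$states == -1L)) "necessary" else "mixed",
        stringsAsFactors = FALSE)
    }
    P <- gen[!sig]
    k <- k + 1L
  }
  if (!length(results)) return(empty)
  out <- do.call(rbind, results)
  out[order(out$k, out$tf_states), , drop = FALSE]
}

#' Mine multi-TF interactions across all modules
#'
#' Runs [mine_module()] per module and returns the stacked results in a
#' deterministic (module, k, TF ids) order.
#'
#' @param modules `regulatory_modules`.
#' @inheritParams mine_module
#' @return Data frame as in [mine_module()].
#' @export
mine_interactions <- function(modules, expr, singles = NULL, alpha = 0.05,
                              max_k = Inf) {
  parts <- lapply(modules, mine_module, expr = expr,
                  singles = singles, alpha = alpha, max_k = max_k)
  out <- if (length(parts)) do.call(rbind, parts) else {
    data.frame(module_id = character(), k = integer(), tf_states = character(),
               g_state = character(), afn_score = numeric(), p_value = numeric(),
               logic = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$module_id, out$k, out$tf_states), , drop = FALSE]
}
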