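#' Atomic individual-TF interaction labels
#'
#' `AN`/`AS` = activator necessary/sufficient, `RN`/`RS` = repressor
#' necessary/sufficient. This fixed order is also the deterministic
#' tie-break order used by the EM labeler.
#'
#' @return Character vector of the four atomic labels.
#' @export
atomic_labels <- function() c("AN", "AS", "RN", "RS")

# (tf state, gene state) pattern that each atomic label asserts
.label_states <- list(
  AN = c(tf = -1L, g = -1L),  # necessary activator: TF down forces gene down
  AS = c(tf = 1L,  g = 1L),   # sufficient activator: TF up forces gene up
  RN = c(tf = -1L, g = 1L),   # necessary repressor: TF down releases gene up
  RS = c(tf = 1L,  g = -1L)   # sufficient repressor: TF up forces gene down
)

#' Expression-agreement indicator for an atomic label
#'
#' Returns 1 exactly when the (TF state, gene state) pair matches the
#' label's asserted pattern: (up, up) for AS, (up, down) for RS,
#' (down, down) for AN and (down, up) for RN. A no-change state in either
#' argument never matches.
#'
#' @param label One of `"AN"`, `"AS"`, `"RN"`, `"RS"`.
#' @param tf_state,g_state Ternary states (`-1`/`0`/`1`), vectorized.
#' @return Integer 0/1 vector.
#' @export
gamma_match <- function(label, tf_state, g_state) {
  if (length(label) != 1L || !label %in% atomic_labels()) {
    stop_input("gamma_match requires a single atomic label (AN, AS, RN, RS)")
  }
  st <- .label_states[[label]]
  as.integer(tf_state == st[["tf"]] & g_state == st[["g"]])
}

# Match count for one (module, TF, label): sum of gamma over all time
# points and all module genes.
match_count <- function(tf_row, gene_mat, label) {
  st <- .label_states[[label]]
  cnt_g <- colSums(gene_mat == st[["g"]])       # genes matching per time point
  sum(cnt_g[tf_row == st[["tf"]]])
}

# Match-count table over all (module, TF) pairs x atomic labels.
# Rows follow the module order, TFs in module (sorted) order.
match_count_table <- function(modules, expr) {
  pairs <- do.call(rbind, lapply(modules, function(m) {
    data.frame(module_id = m$module_id, tf_id = m$tfs, stringsAsFactors = FALSE)
  }))
  missing_rows <- setdiff(
    unique(c(pairs$tf_id, unlist(lapply(modules, `[[`, "genes")))),
    rownames(expr)
  )
  if (length(missing_rows)) {
    stop_input("no expression row for entity '%s'", missing_rows[1L])
  }
  counts <- matrix(0L, nrow(pairs), 4L,
                   dimnames = list(NULL, atomic_labels()))
  i <- 0L
  for (m in modules) {
    gene_mat <- unclass(expr)[m$genes, , drop = FALSE]
    for (tf in m$tfs) {
      i <- i + 1L
      row <- unclass(expr)[tf, ]
      for (lab in atomic_labels()) {
        counts[i, lab] <- match_count(row, gene_mat, lab)
      }
    }
  }
  list(pairs = pairs, counts = counts)
}

#' Likelihood of an atomic label for a TF in a module
#'
#' The numerator counts, over all time points and all genes of the module,
#' the (TF state, gene state) agreements asserted by `label`
#' ([gamma_match()]); the denominator is the same count for the *same
#' label* summed over every (module, TF) pair in `modules`. Returns 0 when
#' the label never matches anywhere. On the built-in illustrative module
#' (see [toy_example()]) the AN likelihood of `tf1` is 12/26.
#'
#' @param tf_id TF identifier (must be a TF of the referenced module).
#' @param label Atomic label.
#' @param modules `regulatory_modules` list.
#' @param expr [ternary_matrix()] holding rows for all TFs and genes.
#' @param module_id Module to evaluate; may be omitted when `tf_id`
#'   belongs to exactly one module.
#' @return Numeric scalar in \[0, 1\].
#' @export
likelihood <- function(tf_id, label, modules, expr, module_id = NULL) {
  tab <- match_count_table(modules, expr)
  if (is.null(module_id)) {
    hit <- tab$pairs$tf_id == tf_id
    if (sum(hit) != 1L) {
      stop_input("tf '%s' is in %d modules; pass module_id", tf_id, sum(hit))
    }
  } else {
    hit <- tab$pairs$tf_id == tf_id & tab$pairs$module_id == module_id
    if (!any(hit)) stop_input("tf '%s' is not a TF of module '%s'", tf_id, module_id)
  }
  denom <- sum(tab$counts[, label])
  if (denom == 0) return(0)
  unname(tab$counts[hit, label] / denom)
}

#' Prior over atomic labels from current assignments
#'
#' The prior of a label is its assignment frequency over all (module, TF)
#' pairs divided by (number of modules x number of TFs).
#'
#' @param assignments Character vector of atomic labels, one per
#'   (module, TF) pair.
#' @param n_modules,n_tfs Module and TF counts (`|R|`, `|TF|`).
#' @return Named numeric vector over the four atomic labels.
#' @export
prior <- function(assignments, n_modules, n_tfs) {
  if (!length(assignments)) stop_input("empty assignment set")
  if (n_modules <= 0 || n_tfs <= 0) stop_input("|R| and |TF| must be positive")
  fre <- table(factor(assignments, levels = atomic_labels()))
  stats::setNames(as.numeric(fre) / (n_modules * n_tfs), atomic_labels())
}

#' Posterior score of a label
#'
#' Product of prior and likelihood.
#'
#' @param pri,lk Prior and likelihood in \[0, 1\].
#' @return `pri * lk`.
#' @export
posterior <- function(pri, lk) {
  stopifnot(all(pri >= 0 & pri <= 1), all(lk >= 0 & lk <= 1))
  pri * lk
}

#' EM labeling of individual TF roles
#'
#' Assigns each (module, TF) pair one atomic label. Likelihoods (which are
#' constant across iterations) are precomputed once. Each iteration
#' computes posteriors (prior x likelihood), then the maximization step
#' picks, per pair, the label with the largest expression-agreement count
#' — maximizing the module score `S(R_k)`, the summed agreement of
#' assigned labels over the module's TFs and genes — with ties broken by
#' the fixed label order AN < AS < RN < RS, and recomputes the priors from
#' the assignment frequencies. Iteration stops when assignments are
#' unchanged and the largest posterior change falls below `tol`, or after
#' `max_iter` iterations. The initial assignment is a uniform random draw
#' of atomic labels (seeded); the converged assignment does not depend on
#' it.
#'
#' @param modules `regulatory_modules` list (non-empty).
#' @param expr [ternary_matrix()].
#' @param max_iter,tol,seed EM controls.
#' @return List with `pairs` (module_id, tf_id), `counts`, `likelihoods`,
#'   `priors`, `posteriors`, `assignments`, `S` (named per module),
#'   `iterations`, `converged`.
#' @export
run_em <- function(modules, expr, max_iter = 100L, tol = 1e-6, seed = 1L) {
  if (!length(modules)) stop_input("run_em requires at least one module")
  tab <- match_count_table(modules, expr)
  counts <- tab$counts
  denom <- colSums(counts)
  lk <- sweep(counts, 2L, ifelse(denom > 0, denom, 1), `/`)
  lk[, denom == 0] <- 0
  n_modules <- length(modules)
  n_tfs <- length(unique(tab$pairs$tf_id))
  labs <- atomic_labels()

  assignments <- with_seed(seed, sample(labs, nrow(counts), replace = TRUE))
  priors <- stats::setNames(rep(0.25, 4L), labs)
  post <- sweep(lk, 2L, priors, `*`)
  iterations <- 0L
  converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    # maximization: per-pair argmax of the agreement count (ties by order)
    new_assign <- labs[apply(counts, 1L, which.max)]
    new_priors <- prior(new_assign, n_modules, n_tfs)
    new_post <- sweep(lk, 2L, new_priors, `*`)
    stable <- identical(new_assign, assignments) &&
      max(abs(new_post - post)) < tol
    assignments <- new_assign
    priors <- new_priors
    post <- new_post
    if (stable) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  S <- vapply(modules, function(m) {
    idx <- tab$pairs$module_id == m$module_id
    sum(counts[cbind(which(idx), match(assignments[idx], labs))])
  }, 0)
  names(S) <- vapply(modules, `[[`, "", "module_id")
  message(sprintf("EM labeling converged=%s after %d iteration(s); S: %s",
                  converged, iterations,
                  paste(sprintf("%s=%d", names(S), as.integer(S)), collapse = " ")))
  list(pairs = tab$pairs, counts = counts, likelihoods = lk, priors = priors,
       posteriors = post, assignments = assignments, S = S,
       iterations = iterations, converged = converged)
}

# Permutation p-values for all four labels of one (module, TF) pair.
# The statistic is the posterior with the prior and the global likelihood
# denominator held at their fitted values; only the TF's time profile is
# permuted. B random permutations share one stream; add-one p-values.
perm_pvalues_pair <- function(tf_row, gene_mat, priors, denom, B = 999L) {
  T <- length(tf_row)
  labs <- atomic_labels()
  cnt <- list(
    up = colSums(gene_mat == TERNARY_UP),
    down = colSums(gene_mat == TERNARY_DOWN)
  )
  ind <- list(up = tf_row == TERNARY_UP, down = tf_row == TERNARY_DOWN)
  obs_num <- c(
    AN = sum(cnt$down[ind$down]), AS = sum(cnt$up[ind$up]),
    RN = sum(cnt$up[ind$down]), RS = sum(cnt$down[ind$up])
  )
  scale_fac <- ifelse(denom[labs] > 0, priors[labs] / pmax(denom[labs], 1), 0)
  obs <- obs_num[labs] * scale_fac
  exceed <- stats::setNames(numeric(4L), labs)
  for (b in seq_len(B)) {
    p <- sample.int(T)
    iu <- ind$up[p]; idn <- ind$down[p]
    null_num <- c(
      AN = sum(cnt$down[idn]), AS = sum(cnt$up[iu]),
      RN = sum(cnt$up[idn]), RS = sum(cnt$down[iu])
    )
    exceed <- exceed + (null_num[labs] * scale_fac >= obs)
  }
  (1 + exceed) / (B + 1)
}

#' Permutation p-value for one TF label in a module
#'
#' The null distribution is obtained by randomly permuting the TF's time
#' profile `B` times and recomputing the posterior with the prior and the
#' global likelihood denominator held fixed; the p-value is
#' `(1 + #\{null >= observed\}) / (B + 1)`, always in (0, 1].
#'
#' @param tf_id TF identifier.
#' @param module One module (list with `genes`).
#' @param label Atomic label.
#' @param expr [ternary_matrix()].
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param priors Named prior vector (default uniform 0.25).
#' @param denom Named global match-count denominators per label; defaults
#'   to this module's own counts (single-module context).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(tf_id, module, label, expr, B = 999L, seed = 1L,
                               priors = stats::setNames(rep(0.25, 4), atomic_labels()),
                               denom = NULL) {
  if (B < 100L) stop_input("B must be >= 100")
  gene_mat <- unclass(expr)[module$genes, , drop = FALSE]
  tf_row <- unclass(expr)[tf_id, ]
  if (is.null(denom)) {
    denom <- vapply(atomic_labels(), function(l) match_count(tf_row, gene_mat, l), 0)
  }
  p <- with_seed(seed, perm_pvalues_pair(tf_row, gene_mat, priors, denom, B))
  unname(p[label])
}

#' Classify a TF's individual role from posteriors and p-values
#'
#' `NoDecision` when no atomic label is significant at `alpha`. When both
#' the necessary and the sufficient label of one direction (AN and AS, or
#' RN and RS) are significant and their posteriors differ by less than
#' `eps`, the combined label `ANS` (resp. `RNS`) is returned. Otherwise
#' the significant label with the highest posterior wins (ties broken by
#' the fixed label order).
#'
#' @param posteriors,p_values Named numeric vectors over the four atomic
#'   labels.
#' @param alpha Significance threshold on the permutation p-values.
#' @param eps Posterior closeness threshold for the combined labels.
#' @return Single label string.
#' @export
classify <- function(posteriors, p_values, alpha = 0.05, eps = 0.05) {
  labs <- atomic_labels()
  stopifnot(all(labs %in% names(posteriors)), all(labs %in% names(p_values)))
  sig <- p_values[labs] < alpha
  if (!any(sig)) return("NoDecision")
  if (sig[["AN"]] && sig[["AS"]] &&
      abs(posteriors[["AN"]] - posteriors[["AS"]]) < eps) return("ANS")
  if (sig[["RN"]] && sig[["RS"]] &&
      abs(posteriors[["RN"]] - posteriors[["RS"]]) < eps) return("RNS")
  cand <- labs[sig]
  cand[which.max(posteriors[cand])]
}

#' Infer individual TF roles for all modules
#'
#' Runs the EM labeling ([run_em()]), computes permutation p-values for
#' every (module, TF, label), and classifies each pair ([classify()]).
#'
#' @param modules `regulatory_modules`.
#' @param expr [ternary_matrix()].
#' @param alpha,eps Classification thresholds.
#' @param B Permutations per (module, TF).
#' @param max_iter,tol EM controls.
#' @param seed Integer seed for the EM initialization and permutations.
#' @return List with `results` (data frame: module_id, tf_id, label,
#'   posterior, p_value — `p_value` is `NA` for NoDecision) and `fit`
#'   (the [run_em()] output plus per-label p-values).
#' @export
infer_individual <- function(modules, expr, alpha = 0.05, eps = 0.05,
                             B = 999L, max_iter = 100L, tol = 1e-6, seed = 1L) {
  fit <- run_em(modules, expr, max_iter = max_iter, tol = tol, seed = seed)
  denom <- colSums(fit$counts)
  labs <- atomic_labels()
  module_by_id <- stats::setNames(modules, vapply(modules, `[[`, "", "module_id"))
  n <- nrow(fit$pairs)
  pvals <- matrix(NA_real_, n, 4L, dimnames = list(NULL, labs))
  results <- with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      m <- module_by_id[[fit$pairs$module_id[i]]]
      gene_mat <- unclass(expr)[m$genes, , drop = FALSE]
      tf_row <- unclass(expr)[fit$pairs$tf_id[i], ]
      pvals[i, ] <- perm_pvalues_pair(tf_row, gene_mat, fit$priors, denom, B)
      lab <- classify(fit$posteriors[i, ], pvals[i, ], alpha = alpha, eps = eps)
      post_i <- fit$posteriors[i, ]
      p_i <- pvals[i, ]
      if (lab == "NoDecision") {
        po <- max(post_i); pv <- NA_real_
      } else if (lab == "ANS") {
        po <- max(post_i[c("AN", "AS")]); pv <- max(p_i[c("AN", "AS")])
      } else if (lab == "RNS") {
        po <- max(post_i[c("RN", "RS")]); pv <- max(p_i[c("RN", "RS")])
      } else {
        po <- post_i[[lab]]; pv <- p_i[[lab]]
      }
      rows[[i]] <- data.frame(module_id = fit$pairs$module_id[i],
                              tf_id = fit$pairs$tf_id[i], label = lab,
                              posterior = po, p_value = pv,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  fit$label_pvalues <- pvals
  list(results = results, fit = fit)
}
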