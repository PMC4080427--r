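# Shared fixtures and independent oracles for the test suite.

# random ternary matrix with given row ids
rand_ternary <- function(ids, T, seed, probs = c(0.35, 0.3, 0.35)) {
  set.seed(seed)
  ternary_matrix(matrix(sample(c(1L, 0L, -1L), length(ids) * T, replace = TRUE,
                               prob = probs),
                        nrow = length(ids), dimnames = list(ids, NULL)))
}

make_module <- function(tfs, genes, id = "M001") {
  list(module_id = id, tfs = sort(tfs), genes = genes, cluster = "1")
}

# --- naive counting oracles (independent of the package's scorer) --------

naive_pattern_count <- function(expr, genes, tf_states = NULL, g_state = NULL) {
  x <- unclass(expr)
  count <- 0L
  for (t in seq_len(ncol(x))) {
    ok <- TRUE
    for (i in seq_along(tf_states)) {
      if (x[names(tf_states)[i], t] != tf_states[[i]]) { ok <- FALSE; break }
    }
    if (!ok) next
    for (g in genes) {
      if (is.null(g_state) || x[g, t] == g_state) count <- count + 1L
    }
  }
  count
}

naive_afn <- function(expr, genes, tf_states, g_state) {
  N <- ncol(expr) * length(genes)
  p_tf <- naive_pattern_count(expr, genes, tf_states = tf_states) / N
  if (p_tf == 0) return(0)
  p_joint <- naive_pattern_count(expr, genes, tf_states, g_state) / N
  p_g <- naive_pattern_count(expr, genes, NULL, g_state) / N
  p_joint * p_g / p_tf
}

oracle_key <- function(tfs, states, dir) {
  paste0(dir, "|", paste(tfs, states, sep = ":", collapse = ";"))
}

# all k-TF candidates of a TF set (plain enumeration)
oracle_enumerate <- function(tfs, k) {
  out <- list()
  for (cb in utils::combn(sort(tfs), k, simplify = FALSE)) {
    grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), k)))
    for (r in seq_len(nrow(grid))) {
      for (d in c(1L, -1L)) {
        out[[length(out) + 1L]] <- list(tfs = cb, states = unname(grid[r, ]), dir = d)
      }
    }
  }
  out
}

# brute-force level-wise miner: plain lists and set algebra, naive counting
oracle_mine <- function(module, expr, singles = NULL, alpha = 0.05) {
  genes <- module$genes
  tfs <- sort(module$tfs)
  m <- length(tfs)
  pat_map <- list(AN = list(c(-1L, -1L)), AS = list(c(1L, 1L)),
                  RN = list(c(-1L, 1L)), RS = list(c(1L, -1L)),
                  ANS = list(c(-1L, -1L), c(1L, 1L)),
                  RNS = list(c(-1L, 1L), c(1L, -1L)))
  sig_keys <- character()
  if (!is.null(singles) && nrow(singles)) {
    here <- singles[singles$module_id == module$module_id &
                      singles$label != "NoDecision", , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      for (p in pat_map[[here$label[i]]]) {
        sig_keys <- c(sig_keys, oracle_key(here$tf_id[i], p[1L], p[2L]))
      }
    }
  }
  P <- list()
  for (tf in tfs) for (s in c(1L, -1L)) for (d in c(1L, -1L)) {
    if (oracle_key(tf, s, d) %in% sig_keys) next
    if (naive_pattern_count(expr, genes, stats::setNames(s, tf), d) > 0) {
      P[[length(P) + 1L]] <- list(tfs = tf, states = s, dir = d)
    }
  }
  reported <- list()
  k <- 2L
  while (k <= m && length(P) >= 2L) {
    pkeys <- vapply(P, function(c) oracle_key(c$tfs, c$states, c$dir), "")
    all_k <- oracle_enumerate(tfs, k)
    pop <- vapply(all_k, function(c) {
      naive_afn(expr, genes, stats::setNames(c$states, c$tfs), c$dir)
    }, 0)
    gen <- Filter(function(c) {
      subkeys <- vapply(seq_len(k), function(j) {
        oracle_key(c$tfs[-j], c$states[-j], c$dir)
      }, "")
      sum(subkeys %in% pkeys) >= 2L
    }, all_k)
    gen <- Filter(function(c) {
      for (size in seq_len(k - 1L)) {
        for (idx in utils::combn(k, size, simplify = FALSE)) {
          if (oracle_key(c$tfs[idx], c$states[idx], c$dir) %in% sig_keys) {
            return(FALSE)
          }
        }
      }
      TRUE
    }, gen)
    if (!length(gen)) break
    scores <- vapply(gen, function(c) {
      naive_afn(expr, genes, stats::setNames(c$states, c$tfs), c$dir)
    }, 0)
    pv <- vapply(scores, function(x) {
      loo <- pop[-match(x, pop)]
      s <- stats::sd(loo)
      if (!is.finite(s) || s == 0) return(1)
      min(1, max(.Machine$double.xmin,
                 stats::pt((x - mean(loo)) / s, df = length(loo) - 1L,
                           lower.tail = FALSE)))
    }, 0)
    sig <- pv < alpha
    for (i in which(sig)) {
      c <- gen[[i]]
      sig_keys <- c(sig_keys, oracle_key(c$tfs, c$states, c$dir))
      reported[[length(reported) + 1L]] <- list(cand = c, score = scores[i],
                                                p = pv[i])
    }
    P <- gen[!sig]
    k <- k + 1L
  }
  reported
}

# canonical keys of a mine_module()/mine_interactions() result table
mined_keys <- function(df) {
  if (!nrow(df)) return(character())
  word_to_num <- c(up = 1L, down = -1L)
  vapply(seq_len(nrow(df)), function(i) {
    parts <- strsplit(strsplit(df$tf_states[i], ";", fixed = TRUE)[[1L]],
                      ":", fixed = TRUE)
    oracle_key(vapply(parts, `[[`, "", 1L),
               word_to_num[vapply(parts, `[[`, "", 2L)],
               word_to_num[df$g_state[i]])
  }, "")
}
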