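tx <- toy_example()
genes <- tx$modules[[1]]$genes

test_that("pattern probabilities count (time point, gene) pairs", {
  expect_equal(pattern_probability(tx$expr, genes,
                                   tf_states = c(tf1 = 1L, tf2 = 1L, tf3 = -1L)),
               12 / 24)
  expect_equal(pattern_probability(tx$expr, genes, g_state = 1L), 10 / 24)
  expect_equal(pattern_probability(tx$expr, genes, tf_states = c(tf3 = 1L)), 0)
  expect_error(pattern_probability(tx$expr, genes), "empty pattern")
  expect_error(pattern_probability(tx$expr, character(), g_state = 1L),
               "non-empty gene set")
  expect_error(pattern_probability(tx$expr, genes, tf_states = c(zz = 1L)), "'zz'")
})

test_that("affinity scores reproduce the worked example", {
  expect_equal(afn_score(tx$expr, genes, c(tf1 = 1L, tf2 = 1L, tf3 = -1L), 1L),
               100 / 288)
  expect_equal(afn_score(tx$expr, genes, c(tf1 = 1L, tf2 = 1L), 1L), 100 / 288)
  expect_equal(afn_score(tx$expr, genes, c(tf2 = 1L, tf3 = -1L), 1L), 100 / 576)
  expect_equal(afn_score(tx$expr, genes, c(tf1 = 1L, tf3 = -1L), 1L), 100 / 288)
  # TF pattern that never occurs -> guarded zero
  expect_equal(afn_score(tx$expr, genes, c(tf3 = 1L), 1L), 0)
})

test_that("affinity equals P(target | pattern) * P(target) and is bounded", {
  for (s in 1:12) {
    expr <- rand_ternary(c("A", "B", "g1", "g2", "g3"), 25, seed = s)
    gs <- c("g1", "g2", "g3")
    tfst <- c(A = sample(c(1L, -1L), 1), B = sample(c(1L, -1L), 1))
    d <- sample(c(1L, -1L), 1)
    score <- afn_score(expr, gs, tfst, d)
    p_pat <- pattern_probability(expr, gs, tf_states = tfst)
    p_g <- pattern_probability(expr, gs, g_state = d)
    if (p_pat > 0) {
      cond <- pattern_probability(expr, gs, tfst, d) / p_pat
      expect_equal(score, cond * p_g)
    }
    expect_gte(score, 0)
    expect_lte(score, p_g)
    expect_lte(score, 1)
  }
})

test_that("candidate space counts match explicit enumeration", {
  expect_equal(count_candidate_space(3), 40L)
  expect_equal(count_candidate_space(2), 8L)
  expect_equal(count_candidate_space(1), 0L)
  expect_equal(count_candidate_space(0), 0L)
  for (m in 2:6) {
    tfs <- paste0("T", seq_len(m))
    n <- sum(vapply(2:m, function(k) length(enumerate_candidates(tfs, k)), 0L))
    expect_equal(count_candidate_space(m), n)
  }
})

test_that("combinable merging joins on shared constraints only", {
  i2 <- list(tfs = c("tf2", "tf3"), states = c(1L, -1L), dir = 1L)
  i3 <- list(tfs = c("tf1", "tf3"), states = c(1L, -1L), dir = 1L)
  merged <- combine_candidates(i2, i3)
  expect_equal(merged$tfs, c("tf1", "tf2", "tf3"))
  expect_equal(merged$states, c(1L, 1L, -1L))
  expect_equal(merged$dir, 1L)
  # different target directions never merge
  expect_null(combine_candidates(i2, list(tfs = c("tf1", "tf3"),
                                          states = c(1L, -1L), dir = -1L)))
  # same TF constrained to two states never merges
  expect_null(combine_candidates(i2, list(tfs = c("tf2", "tf3"),
                                          states = c(-1L, -1L), dir = 1L)))
  # identical candidates never merge
  expect_null(combine_candidates(i2, i2))
  expect_error(combine_candidates(list(tfs = c("tf3", "tf1"),
                                       states = c(1L, 1L), dir = 1L), i2),
               "sorted")
})

test_that("candidate index round-trips and subset pruning matches brute force", {
  idx <- candidate_index()
  index_insert(idx, c("a", "b"), c(1L, -1L), 1L)
  expect_true(index_contains(idx, c("a", "b"), c(1L, -1L), 1L))
  expect_false(index_contains(idx, c("a", "b"), c(1L, -1L), -1L))
  expect_false(index_contains(idx, c("a", "b"), c(1L, 1L), 1L))

  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    tfs <- sort(paste0("T", sample(1:6, k)))
    cand <- list(tfs = tfs, states = sample(c(1L, -1L), k, replace = TRUE),
                 dir = sample(c(1L, -1L), 1))
    sig <- candidate_index()
    sig_list <- list()
    for (j in 1:3) {
      kk <- sample(1:(k - 1), 1)
      pick <- sort(sample(k, kk))
      sub <- if (runif(1) < 0.5) {
        list(tfs = cand$tfs[pick], states = cand$states[pick], dir = cand$dir)
      } else {
        list(tfs = cand$tfs[pick],
             states = sample(c(1L, -1L), kk, replace = TRUE),
             dir = sample(c(1L, -1L), 1))
      }
      index_insert(sig, sub$tfs, sub$states, sub$dir)
      sig_list[[j]] <- sub
    }
    # brute force: is any delete-one subpattern among the inserted ones?
    brute <- any(vapply(seq_len(k), function(j) {
      any(vapply(sig_list, function(s) {
        identical(s$tfs, cand$tfs[-j]) && identical(s$states, cand$states[-j]) &&
          s$dir == cand$dir
      }, TRUE))
    }, TRUE))
    expect_equal(prune_by_subset(cand, sig), brute)
  }
})

test_that("level p-values are upper-tail and guard degenerate levels", {
  p <- level_pvalues(c(0.9, 0.1, 0.12, 0.11, 0.09, 0.1, 0.12))
  expect_lt(p[1], 0.05)
  expect_true(all(p[-1] > 0.5))
  expect_warning(p1 <- level_pvalues(c(0.5, 0.5)), "fewer than 3")
  expect_equal(p1, c(1, 1))
  expect_equal(level_pvalues(rep(0.3, 5)), rep(1, 5))  # zero variance
  # the worked-example level-2 scores alone are all insignificant
  p2 <- level_pvalues(c(0.347, 0.173, 0.347))
  expect_true(all(p2 >= 0.05))
  expect_true(all(p2 > 0 & p2 <= 1))
})

test_that("the example module yields exactly the three-TF interaction", {
  ind <- suppressMessages(infer_individual(tx$modules, tx$expr, seed = 1))
  out <- mine_interactions(tx$modules, tx$expr, singles = ind$results)
  expect_equal(nrow(out), 1L)
  expect_equal(out$k, 3L)
  expect_equal(out$tf_states, "tf1:up;tf2:up;tf3:down")
  expect_equal(out$g_state, "up")
  expect_equal(out$afn_score, 100 / 288)
  expect_lt(out$p_value, 0.05)
  expect_equal(out$logic, "mixed")
})

test_that("a decisive TF pair is reported at level 2 and blocks its supersets", {
  # T1 up AND T2 up forces the target up; a third bound TF is independent
  set.seed(8)
  T <- 48
  t1 <- sample(c(1L, -1L), T, replace = TRUE)
  t2 <- sample(c(1L, -1L), T, replace = TRUE)
  t3 <- sample(c(1L, 0L, -1L), T, replace = TRUE)
  g <- ifelse(t1 == 1L & t2 == 1L, 1L,
              sample(c(0L, -1L), T, replace = TRUE, prob = c(0.7, 0.3)))
  expr <- ternary_matrix(rbind(T1 = t1, T2 = t2, T3 = t3, g1 = as.integer(g)))
  mod <- make_module(c("T1", "T2", "T3"), "g1")
  out <- mine_module(mod, expr, singles = NULL)
  keys <- mined_keys(out)
  expect_true(oracle_key(c("T1", "T2"), c(1L, 1L), 1L) %in% keys)
  expect_false(any(out$k == 3 & grepl("T1:up", out$tf_states) &
                     grepl("T2:up", out$tf_states) & out$g_state == "up"))
})

test_that("mining equals the brute-force oracle on random small modules", {
  set.seed(303)
  n_checked <- 0L
  for (rep in 1:25) {
    m <- sample(2:4, 1)
    n_g <- sample(1:3, 1)
    tfs <- paste0("T", seq_len(m))
    gs <- paste0("g", seq_len(n_g))
    expr <- rand_ternary(c(tfs, gs), T = sample(15:50, 1), seed = 5000 + rep)
    mod <- make_module(tfs, gs)
    # occasionally inject a significant stage-1 label to exercise pruning
    singles <- if (rep %% 3 == 0) {
      data.frame(module_id = "M001", tf_id = sample(tfs, 1),
                 label = sample(c(atomic_labels(), "ANS"), 1),
                 stringsAsFactors = FALSE)
    }
    got <- mine_module(mod, expr, singles = singles)
    want <- oracle_mine(mod, expr, singles = singles)
    want_keys <- sort(vapply(want, function(r) {
      oracle_key(r$cand$tfs, r$cand$states, r$cand$dir)
    }, ""))
    expect_identical(sort(mined_keys(got)), want_keys, label = paste("rep", rep))
    if (length(want)) {
      n_checked <- n_checked + 1L
      ord <- match(sort(mined_keys(got)), mined_keys(got))
      want_ord <- order(vapply(want, function(r) {
        oracle_key(r$cand$tfs, r$cand$states, r$cand$dir)
      }, ""))
      expect_equal(got$afn_score[ord],
                   vapply(want, `[[`, 0, "score")[want_ord], tolerance = 1e-12)
      expect_equal(got$p_value[ord],
                   vapply(want, `[[`, 0, "p")[want_ord], tolerance = 1e-9)
    }
  }
  expect_gt(n_checked, 3L)  # the comparison exercised non-empty outputs
})

test_that("reported interactions are minimal under re-testing", {
  set.seed(77)
  for (rep in 1:6) {
    tfs <- paste0("T", 1:4)
    expr <- rand_ternary(c(tfs, "g1", "g2"), 40, seed = 600 + rep)
    mod <- make_module(tfs, c("g1", "g2"))
    out <- mine_module(mod, expr)
    if (!nrow(out)) next
    keys <- mined_keys(out)
    for (key in keys) {
      # no reported interaction may contain another reported one
      others <- setdiff(keys, key)
      parts <- strsplit(sub("^[-0-9]+\\|", "", key), ";")[[1]]
      dir <- sub("\\|.*", "", key)
      for (o in others) {
        oparts <- strsplit(sub("^[-0-9]+\\|", "", o), ";")[[1]]
        odir <- sub("\\|.*", "", o)
        expect_false(odir == dir && all(oparts %in% parts))
      }
    }
  }
})

test_that("per-candidate false positives under the null are near alpha", {
  # random expression, no planted structure: each candidate's level test
  # should flag about alpha of the candidate population
  set.seed(99)
  n_cand <- 0L; n_sig <- 0L
  for (rep in 1:30) {
    tfs <- paste0("T", 1:3)
    expr <- rand_ternary(c(tfs, "g1"), 60, seed = 9000 + rep)
    pop <- vapply(oracle_enumerate(tfs, 2), function(c) {
      naive_afn(expr, "g1", stats::setNames(c$states, c$tfs), c$dir)
    }, 0)
    pv <- level_pvalues(pop)
    n_cand <- n_cand + length(pv)
    n_sig <- n_sig + sum(pv < 0.05)
  }
  rate <- n_sig / n_cand
  expect_lt(rate, 0.10)   # calibrated per candidate, allowing sampling slack
})
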