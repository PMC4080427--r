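tx <- toy_example()

test_that("gamma agreement indicator matches the role definitions", {
  expect_equal(gamma_match("AS", 1L, 1L), 1L)
  expect_equal(gamma_match("AS", -1L, 1L), 0L)
  expect_equal(gamma_match("RN", -1L, 1L), 1L)
  expect_equal(gamma_match("RS", 1L, -1L), 1L)
  expect_equal(gamma_match("AN", -1L, -1L), 1L)
  expect_equal(gamma_match("AN", 0L, -1L), 0L)   # no-change never matches
  expect_equal(gamma_match("AS", 1L, 0L), 0L)
  expect_error(gamma_match("ANS", 1L, 1L), "atomic")
})

test_that("likelihoods use the same-label global denominator", {
  expect_equal(likelihood("tf1", "AN", tx$modules, tx$expr), 12 / 26)
  expect_equal(likelihood("tf2", "AN", tx$modules, tx$expr), 0)
  # direct count over the example: tf3 down & genes down at 7 time points x 2
  expect_equal(likelihood("tf3", "AN", tx$modules, tx$expr), 14 / 26)
  expect_error(likelihood("zz", "AN", tx$modules, tx$expr), "'zz'")
})

test_that("per-label likelihoods sum to one over all (module, TF) pairs", {
  ids <- c(paste0("T", 1:4), paste0("g", 1:5))
  expr <- rand_ternary(ids, 30, seed = 9)
  mods <- structure(list(
    make_module(c("T1", "T2"), c("g1", "g2"), "M001"),
    make_module(c("T2", "T3", "T4"), c("g3", "g4", "g5"), "M002")
  ), class = "regulatory_modules")
  fit <- suppressMessages(run_em(mods, expr))
  sums <- colSums(fit$likelihoods)
  nonzero <- colSums(fit$counts) > 0
  expect_equal(unname(sums[nonzero]), rep(1, sum(nonzero)))
})

test_that("priors are assignment frequencies over |R| x |TF|", {
  expect_equal(unname(prior(rep("AN", 3), 1, 3)), c(1, 0, 0, 0))
  expect_equal(prior(c("AN", "AN", "AS", "RS"), 2, 2)[["AN"]], 0.5)
  expect_error(prior(character(), 1, 1), "empty")
  expect_equal(posterior(0.70, 12 / 26), 0.323, tolerance = 1e-3)
  expect_equal(posterior(0, 0.9), 0)
  expect_equal(posterior(1, 0.25), 0.25)
})

test_that("posterior ranking is invariant to scaling all priors", {
  lk <- c(0.4, 0.3, 0.2, 0.1)
  pri <- c(0.1, 0.2, 0.3, 0.4)
  expect_identical(order(posterior(pri, lk)), order(posterior(pri * 0.37, lk)))
  expect_identical(order(posterior(pri, lk)), order(posterior(pri * 2.5, lk)))
})

test_that("EM labeling of the example is AN for tf1, for any seed", {
  labs <- vapply(1:10, function(s) {
    fit <- suppressMessages(run_em(tx$modules, tx$expr, seed = s))
    expect_true(fit$converged)
    expect_lt(fit$iterations, 100L)
    fit$assignments[fit$pairs$tf_id == "tf1"]
  }, "")
  expect_identical(unique(labs), "AN")
})

test_that("a perfectly sufficient activator is labeled AS immediately", {
  expr <- ternary_matrix(matrix(
    1L, nrow = 2, ncol = 10, dimnames = list(c("T1", "g1"), NULL)))
  mods <- structure(list(make_module("T1", "g1")), class = "regulatory_modules")
  fit <- suppressMessages(run_em(mods, expr))
  expect_identical(fit$assignments, "AS")
  # own counts are the only mass
  expect_equal(fit$likelihoods[1, "AS"], 1, ignore_attr = TRUE)
  expect_equal(fit$posteriors[1, "AS"], 1, ignore_attr = TRUE)
})

test_that("permutation p-values detect a perfect match and guard degeneracy", {
  set.seed(4)
  tf <- sample(rep(c(1L, -1L), 10))
  expr <- ternary_matrix(rbind(T1 = tf, g1 = tf))
  mod <- make_module("T1", "g1")
  p <- permutation_pvalue("T1", mod, "AS", expr, B = 999, seed = 2)
  expect_lte(p, 0.01)
  # all-no-change profile: observed posterior 0, p = 1
  expr0 <- ternary_matrix(rbind(T1 = rep(0L, 20), g1 = tf))
  expect_equal(permutation_pvalue("T1", mod, "AS", expr0, B = 100, seed = 2), 1)
  expect_gt(p, 0)
  expect_error(permutation_pvalue("T1", mod, "AS", expr, B = 50), ">= 100")
})

test_that("classification follows the significance and closeness rules", {
  post <- c(AN = 0.40, AS = 0.10, RN = 0.05, RS = 0.02)
  pv_only_an <- c(AN = 0.01, AS = 0.5, RN = 0.5, RS = 0.5)
  expect_equal(classify(post, pv_only_an), "AN")
  post2 <- c(AN = 0.40, AS = 0.41, RN = 0, RS = 0)
  pv_both <- c(AN = 0.01, AS = 0.01, RN = 1, RS = 1)
  expect_equal(classify(post2, pv_both, eps = 0.05), "ANS")
  expect_equal(classify(post2 + c(0.3, 0, 0, 0), pv_both, eps = 0.05), "AN")
  expect_equal(classify(post, c(AN = 0.5, AS = 0.5, RN = 0.5, RS = 0.5)),
               "NoDecision")
  post3 <- c(AN = 0, AS = 0, RN = 0.3, RS = 0.28)
  pv3 <- c(AN = 1, AS = 1, RN = 0.01, RS = 0.02)
  expect_equal(classify(post3, pv3), "RNS")
})

test_that("stage 1 on the example: tf1 necessary activator, others undecided", {
  ind <- suppressMessages(infer_individual(tx$modules, tx$expr, seed = 3))
  res <- ind$results
  expect_equal(res$label[res$tf_id == "tf1"], "AN")
  expect_lt(res$p_value[res$tf_id == "tf1"], 0.05)
  expect_equal(res$label[res$tf_id == "tf2"], "NoDecision")
  expect_equal(res$label[res$tf_id == "tf3"], "NoDecision")
  expect_true(all(is.na(res$p_value[res$label == "NoDecision"])))
})

test_that("EM + classification recovers a planted atomic label without noise", {
  for (lab in atomic_labels()) {
    set.seed(match(lab, atomic_labels()) * 17)
    T <- 120
    tf <- sample(c(1L, 0L, -1L), T, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    st <- list(AN = c(-1L, -1L), AS = c(1L, 1L), RN = c(-1L, 1L), RS = c(1L, -1L))[[lab]]
    g <- ifelse(tf == st[1], st[2],
                sample(c(0L, 1L, -1L), T, replace = TRUE, prob = c(0.8, 0.1, 0.1)))
    expr <- ternary_matrix(rbind(T1 = tf, g1 = as.integer(g)))
    mods <- structure(list(make_module("T1", "g1")), class = "regulatory_modules")
    ind <- suppressMessages(infer_individual(mods, expr, seed = 5))
    expect_equal(ind$results$label, lab, label = paste("planted", lab))
  }
})
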