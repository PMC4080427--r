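#' Default parameters of the benchmark synthetic network
#'
#' The reference configuration for the synthetic benchmark: 11 TFs and 17
#' target genes (28 nodes), 58 edges of which 12 (20.69%) are binding-only
#' decoys, two feed-forward loops, and 500-time-point expression series
#' simulated at a 10% or 40% noise rate.
#'
#' @return List of generator parameters.
#' @export
figure_defaults <- function() {
  list(n_tf = 11L, n_targets = 17L, n_edges = 58L, n_decoy = 12L,
       n_ffl = 2L, T = 500L, noise_rates = c(0.10, 0.40),
       decoy_fraction = 12 / 58)
}

#' Generate a synthetic TF-DNA binding network skeleton
#'
#' Random bipartite topology plus feed-forward loops: each feed-forward
#' loop contributes a TF -> TF edge and both TFs binding a common target;
#' every target is bound by at least one TF; exactly `n_decoy` TF ->
#' target edges are flagged binding-only (decoys that never influence
#' expression). Per-target regulatory-rule sizes are drawn in 1..3 TFs
#' (feed-forward targets have the 2-TF rule of their loop) and decoy
#' bindings are spread so that the printed edge totals are met; bound TF
#' sets are capped at 6 per target.
#'
#' @param n_tf,n_targets Node counts.
#' @param n_edges Total edges (including TF -> TF loop edges).
#' @param n_decoy Number of binding-only edges.
#' @param n_ffl Number of feed-forward loops.
#' @param seed Integer seed (the skeleton is deterministic given it).
#' @return `synthetic_truth` skeleton: list with `network`
#'   ([binding_network()]), `decoy` (logical per network edge),
#'   `regulated_tfs` (downstream loop TFs and their upstream regulator),
#'   `rule_tfs` (per-target regulatory TF sets), `params`.
#' @export
generate_network <- function(n_tf = 11L, n_targets = 17L, n_edges = 58L,
                             n_decoy = 12L, n_ffl = 2L, seed = 1L) {
  if (2L * n_ffl > n_tf) stop_infeasible("not enough TFs for %d feed-forward loops", n_ffl)
  if (n_ffl > n_targets) stop_infeasible("not enough targets for %d feed-forward loops", n_ffl)
  n_tf_gene <- n_edges - n_ffl          # TF->TF loop edges use part of the budget
  if (n_tf_gene < n_targets + n_decoy) {
    stop_infeasible("edge budget %d too small for %d targets plus %d decoys",
                    n_edges, n_targets, n_decoy)
  }
  cap <- min(n_tf, 6L)
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  targets <- sprintf("G%02d", seq_len(n_targets))

  with_seed(seed, {
    ffl_tfs <- if (n_ffl) matrix(sample(tfs, 2L * n_ffl), ncol = 2L) else
      matrix(character(), ncol = 2L)
    ffl_targets <- sample(targets, n_ffl)

    # regulatory-rule sizes: loop targets get their 2-TF loop rule; the
    # remaining rule mass is spread over 1..3 TFs per target
    rule_size <- stats::setNames(rep(NA_integer_, n_targets), targets)
    rule_size[ffl_targets] <- 2L
    others <- setdiff(targets, ffl_targets)
    need <- n_tf_gene - n_decoy - sum(rule_size, na.rm = TRUE)
    if (need < length(others) || need > 3L * length(others)) {
      stop_infeasible("cannot place %d regulatory edges on %d targets with 1-3 TF rules",
                      need, length(others))
    }
    sizes <- rep(1L, length(others))
    while (sum(sizes) < need) {
      i <- sample.int(length(others), 1L)
      if (sizes[i] < 3L) sizes[i] <- sizes[i] + 1L
    }
    rule_size[others] <- sizes

    # decoy bindings per target, capped so bound sets stay small
    decoy_n <- stats::setNames(rep(0L, n_targets), targets)
    placed <- 0L
    while (placed < n_decoy) {
      g <- sample(targets, 1L)
      if (rule_size[g] + decoy_n[g] < cap) {
        decoy_n[g] <- decoy_n[g] + 1L
        placed <- placed + 1L
      }
    }

    rule_tfs <- list()
    edge_tf <- character(); edge_gene <- character(); edge_decoy <- logical()
    for (g in targets) {
      if (g %in% ffl_targets) {
        pair <- ffl_tfs[match(g, ffl_targets), ]
        rules <- sort(pair)
        pool <- setdiff(tfs, rules)
      } else {
        pool <- tfs
        rules <- sort(sample(pool, rule_size[g]))
        pool <- setdiff(pool, rules)
      }
      decoys <- if (decoy_n[g]) sort(sample(pool, decoy_n[g])) else character()
      rule_tfs[[g]] <- rules
      edge_tf <- c(edge_tf, rules, decoys)
      edge_gene <- c(edge_gene, rep(g, length(rules) + length(decoys)))
      edge_decoy <- c(edge_decoy, rep(FALSE, length(rules)), rep(TRUE, length(decoys)))
    }
    # TF -> TF loop edges (upstream regulates downstream, never decoy)
    if (n_ffl) {
      edge_tf <- c(edge_tf, ffl_tfs[, 1L])
      edge_gene <- c(edge_gene, ffl_tfs[, 2L])
      edge_decoy <- c(edge_decoy, rep(FALSE, n_ffl))
    }
    net <- data.frame(tf = edge_tf, gene = edge_gene, stringsAsFactors = FALSE)
    if (anyDuplicated(net)) stop_infeasible("duplicate edge generated; try another seed")
    class(net) <- c("binding_network", class(net))
    regulated_tfs <- if (n_ffl) {
      stats::setNames(ffl_tfs[, 1L], ffl_tfs[, 2L])   # downstream -> upstream
    } else stats::setNames(character(), character())
    structure(list(network = net, decoy = edge_decoy,
                   regulated_tfs = regulated_tfs, rule_tfs = rule_tfs,
                   ffl = if (n_ffl) data.frame(upstream = ffl_tfs[, 1L],
                                               downstream = ffl_tfs[, 2L],
                                               target = ffl_targets,
                                               stringsAsFactors = FALSE) else NULL,
                   params = list(n_tf = n_tf, n_targets = n_targets,
                                 n_edges = n_edges, n_decoy = n_decoy,
                                 n_ffl = n_ffl, seed = seed)),
              class = "synthetic_truth")
  })
}

#' Plant regulatory rules on a synthetic skeleton
#'
#' Every target receives a generating rule over its regulatory TFs: a
#' single-TF rule is an atomic role label (AN/AS/RN/RS, drawn from
#' `mix$label_weights`); a k-TF rule (k >= 2) is a state pattern
#' (each TF up with probability `mix$state_up`) implying a target
#' direction (up with probability `mix$dir_up`). Downstream feed-forward
#' TFs receive a single-TF rule from their upstream regulator, so TF -> TF
#' edges carry expression signal too.
#'
#' @param skeleton Output of [generate_network()].
#' @param mix List: `label_weights` (named over AN/AS/RN/RS), `state_up`,
#'   `dir_up`.
#' @param seed Integer seed.
#' @return `synthetic_truth` with a `rules` table (target, k, tfs, states,
#'   g_state, label) added.
#' @export
plant_interactions <- function(skeleton,
                               mix = list(label_weights = c(AN = 0.25, AS = 0.25,
                                                            RN = 0.25, RS = 0.25),
                                          state_up = 0.5, dir_up = 0.5),
                               seed = 1L) {
  labs <- atomic_labels()
  w <- mix$label_weights[labs]
  with_seed(seed, {
    entries <- list()
    for (tf_dn in names(skeleton$regulated_tfs)) {
      lab <- sample(labs, 1L, prob = w)
      st <- .label_states[[lab]]
      entries[[length(entries) + 1L]] <- data.frame(
        target = tf_dn, k = 1L, tfs = skeleton$regulated_tfs[[tf_dn]],
        states = state_to_word(st[["tf"]]), g_state = state_to_word(st[["g"]]),
        label = lab, stringsAsFactors = FALSE)
    }
    for (g in names(skeleton$rule_tfs)) {
      rtfs <- skeleton$rule_tfs[[g]]
      if (length(rtfs) == 1L) {
        lab <- sample(labs, 1L, prob = w)
        st <- .label_states[[lab]]
        states <- st[["tf"]]; d <- st[["g"]]
      } else {
        lab <- NA_character_
        states <- ifelse(stats::runif(length(rtfs)) < mix$state_up, 1L, -1L)
        d <- if (stats::runif(1L) < mix$dir_up) 1L else -1L
      }
      entries[[length(entries) + 1L]] <- data.frame(
        target = g, k = length(rtfs), tfs = paste(rtfs, collapse = ";"),
        states = paste(state_to_word(states), collapse = ";"),
        g_state = state_to_word(d), label = lab, stringsAsFactors = FALSE)
    }
    skeleton$rules <- do.call(rbind, entries)
    skeleton
  })
}

# simulate one entity's row from a 1-TF atomic label or a k-TF pattern
.simulate_target_row <- function(rule, expr_rows, T, p_free) {
  tfs <- strsplit(rule$tfs, ";", fixed = TRUE)[[1L]]
  states <- word_to_state(strsplit(rule$states, ";", fixed = TRUE)[[1L]])
  d <- word_to_state(rule$g_state)
  forced <- rep(TRUE, T)
  for (i in seq_along(tfs)) forced <- forced & (expr_rows[[tfs[i]]] == states[i])
  row <- ifelse(forced, d,
                sample(c(0L, 1L, -1L), T, replace = TRUE, prob = p_free))
  as.integer(row)
}

#' Simulate ternary time-series expression for a synthetic truth
#'
#' Root TF rows are drawn independently per time point with
#' `P(up) = P(down) = 0.4`, `P(no-change) = 0.2`; regulated (downstream
#' feed-forward) TFs and all targets follow their planted rule: whenever
#' the rule's TF pattern holds, the entity takes the planted direction,
#' otherwise it takes a no-change-biased free draw
#' (`P(nc) = 0.5, P(up) = P(down) = 0.25`). Finally every cell is
#' independently corrupted with probability `noise_rate` by resampling
#' uniformly over the two other states; the corruption mask is recorded in
#' the `"noise_mask"` attribute. Decoy edges never influence any row.
#'
#' @param truth `synthetic_truth` with planted rules.
#' @param T Number of time points (>= 2).
#' @param noise_rate Corruption probability in \[0, 1).
#' @param seed Integer seed.
#' @param p_tf TF state probabilities (up, nochange, down).
#' @param p_free Free-draw probabilities (nochange, up, down).
#' @return [ternary_matrix()] with one row per TF and target;
#'   `attr(, "noise_mask")` is the logical corruption mask.
#' @export
simulate_expression <- function(truth, T = 500L, noise_rate = 0.1, seed = 1L,
                                p_tf = c(up = 0.4, nochange = 0.2, down = 0.4),
                                p_free = c(nochange = 0.5, up = 0.25, down = 0.25)) {
  if (T < 2L) stop_infeasible("T must be >= 2")
  if (noise_rate < 0 || noise_rate >= 1) stop_infeasible("noise_rate must be in [0, 1)")
  if (is.null(truth$rules)) stop_input("truth has no planted rules; call plant_interactions()")
  tfs <- sprintf("TF%02d", seq_len(truth$params$n_tf))
  targets <- sort(names(truth$rule_tfs))
  rules_by_target <- split(truth$rules, truth$rules$target)
  with_seed(seed, {
    rows <- list()
    root_tfs <- setdiff(tfs, names(truth$regulated_tfs))
    for (tf in root_tfs) {
      rows[[tf]] <- sample(c(1L, 0L, -1L), T, replace = TRUE, prob = p_tf)
    }
    # downstream loop TFs follow their upstream rule (upstreams are roots)
    for (tf in names(truth$regulated_tfs)) {
      rows[[tf]] <- .simulate_target_row(rules_by_target[[tf]][1L, ], rows, T,
                                         p_free)
    }
    for (g in targets) {
      rows[[g]] <- .simulate_target_row(rules_by_target[[g]][1L, ], rows, T, p_free)
    }
    entities <- c(tfs, targets)
    mat <- do.call(rbind, rows[entities])
    dimnames(mat) <- list(entities, paste0("t", seq_len(T) - 1L))
    mask <- matrix(stats::runif(length(mat)) < noise_rate, nrow(mat),
                   dimnames = dimnames(mat))
    if (any(mask)) {
      flip <- stats::runif(sum(mask)) < 0.5
      cur <- mat[mask]
      others <- rbind(
        ifelse(cur == 1L, 0L, ifelse(cur == 0L, 1L, 1L)),
        ifelse(cur == 1L, -1L, ifelse(cur == 0L, -1L, 0L))
      )
      mat[mask] <- ifelse(flip, others[1L, ], others[2L, ])
    }
    out <- ternary_matrix(mat)
    attr(out, "noise_mask") <- mask
    out
  })
}

#' Simulate a complete synthetic benchmark dataset
#'
#' Convenience wrapper: [generate_network()] + [plant_interactions()] +
#' [simulate_expression()] with independent sub-seeds derived from `seed`.
#'
#' @param params Parameter list as from [figure_defaults()].
#' @param noise_rate Cell corruption probability.
#' @param seed Integer seed.
#' @param mix Rule mix passed to [plant_interactions()].
#' @return List with `truth` and `expr`.
#' @export
simulate_trn <- function(params = figure_defaults(), noise_rate = 0.1, seed = 1L,
                         mix = list(label_weights = c(AN = 0.25, AS = 0.25,
                                                      RN = 0.25, RS = 0.25),
                                    state_up = 0.5, dir_up = 0.5)) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  skeleton <- generate_network(params$n_tf, params$n_targets, params$n_edges,
                               params$n_decoy, params$n_ffl, seed = seeds[1L])
  truth <- plant_interactions(skeleton, mix = mix, seed = seeds[2L])
  truth$noise_rate <- noise_rate
  truth$T <- params$T
  expr <- simulate_expression(truth, T = params$T, noise_rate = noise_rate,
                              seed = seeds[3L])
  list(truth = truth, expr = expr)
}

#' Write a synthetic truth table as TSV
#' @param truth `synthetic_truth` with rules.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth$rules, path)
  invisible(path)
}
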