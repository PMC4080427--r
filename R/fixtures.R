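#' Built-in illustrative module
#'
#' A minimal worked example: three TFs co-binding two target genes over 12
#' time points. `tf1` is up for the first six time points then down,
#' `tf2` is always up, `tf3` always down, and both targets are up for five
#' time points then down. On this module the individual-role stage labels
#' `tf1` as a necessary activator (its down state forces the targets
#' down), while the miner reports the single three-TF collaboration
#' `<tf1 up, tf2 up, tf3 down> => g up`.
#'
#' The same data ship as plain-text files under
#' `system.file("extdata", package = "tflogic")`.
#'
#' @return List with `expr` ([ternary_matrix()]), `network`
#'   ([binding_network()]), `modules` (a single regulatory module).
#' @export
toy_example <- function() {
  expr <- ternary_matrix(matrix(
    c(rep(1L, 6), rep(-1L, 6),
      rep(1L, 12),
      rep(-1L, 12),
      rep(1L, 5), rep(-1L, 7),
      rep(1L, 5), rep(-1L, 7)),
    nrow = 5, byrow = TRUE,
    dimnames = list(c("tf1", "tf2", "tf3", "g1", "g2"),
                    paste0("t", 0:11))
  ))
  network <- binding_network(
    tf = rep(c("tf1", "tf2", "tf3"), each = 2),
    gene = rep(c("g1", "g2"), times = 3)
  )
  modules <- suppressMessages(build_modules(network))
  list(expr = expr, network = network, modules = modules)
}
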