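#' Ternary expression states
#'
#' Expression changes are coded as three states: up-regulated (`+1L`),
#' down-regulated (`-1L`) and no-change (`0L`). Negating a state swaps up
#' and down and fixes no-change, so ordinary unary minus is the state
#' negation.
#'
#' @name ternary-states
#' @keywords internal
NULL

TERNARY_UP <- 1L
TERNARY_DOWN <- -1L
TERNARY_NOCHANGE <- 0L

.ternary_levels <- c(up = 1L, nochange = 0L, down = -1L)

#' Default token map for ternary text tables
#'
#' Maps text tokens to ternary states when reading/writing pre-ternarized
#' expression tables. Both symbol (`+`/`-`/`0`) and word
#' (`up`/`down`/`nc`) dialects are accepted on input.
#'
#' @return Named integer vector (token -> state).
#' @export
ternary_tokens <- function() {
  c("+" = TERNARY_UP, "-" = TERNARY_DOWN, "0" = TERNARY_NOCHANGE,
    "up" = TERNARY_UP, "down" = TERNARY_DOWN, "nc" = TERNARY_NOCHANGE)
}

#' Construct a ternary expression matrix
#'
#' @param x Integer matrix with values in `{-1, 0, 1}`; rows are
#'   genes/TFs (rownames are the entity ids), columns are time points.
#' @return An integer matrix of class `ternary_matrix`.
#' @export
ternary_matrix <- function(x) {
  if (!is.matrix(x)) stop_input("ternary_matrix expects a matrix")
  storage.mode(x) <- "integer"
  if (any(is.na(x)) || !all(x %in% c(-1L, 0L, 1L))) {
    stop_input("ternary states must be -1, 0 or 1 with no missing values")
  }
  if (is.null(rownames(x))) stop_input("ternary_matrix requires rownames (entity ids)")
  if (anyDuplicated(rownames(x))) stop_input("duplicate entity ids in ternary matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("t", seq_len(ncol(x)) - 1L)
  class(x) <- c("ternary_matrix", class(x))
  x
}

#' @export
print.ternary_matrix <- function(x, ...) {
  cat(sprintf("ternary_matrix: %d entities x %d time points\n", nrow(x), ncol(x)))
  sym <- c(`-1` = "v", `0` = ".", `1` = "^")
  n <- min(nrow(x), 10L)
  m <- min(ncol(x), 30L)
  shown <- matrix(sym[as.character(x[seq_len(n), seq_len(m), drop = FALSE])],
                  nrow = n, dimnames = list(rownames(x)[seq_len(n)], NULL))
  print(apply(shown, 1L, paste, collapse = ""), quote = FALSE)
  invisible(x)
}

#' Is an object a ternary expression matrix?
#' @param x Object.
#' @return Logical scalar.
#' @export
is_ternary_matrix <- function(x) inherits(x, "ternary_matrix")

#' Ternarize a matrix of expression log-ratios
#'
#' Each cell becomes up-regulated when the log-ratio is at least `cutoff`
#' (inclusive), down-regulated when it is at most `-cutoff`, and no-change
#' otherwise. The default cutoff of 0.35 is the conventional change
#' threshold for log-ratio cell-cycle microarray series. Input values must
#' already be log-ratios; consecutive time points are not differenced.
#'
#' @param values Numeric matrix (rows = genes/TFs with rownames, columns =
#'   time points).
#' @param cutoff Positive change threshold on the absolute log-ratio.
#' @return A [ternary_matrix()].
#' @examples
#' m <- matrix(c(0.5, -0.5, 0.1, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
#' ternarize(m)
#' @export
ternarize <- function(values, cutoff = 0.35) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("ternarize expects a numeric matrix")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0) {
    stop_input("cutoff must be a single positive number")
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop_input(sprintf("non-finite expression value at row '%s', column %d",
                       rownames(values)[i[1L]] %||% i[1L], i[2L]))
  }
  out <- matrix(TERNARY_NOCHANGE, nrow(values), ncol(values),
                dimnames = dimnames(values))
  out[values >= cutoff] <- TERNARY_UP
  out[values <= -cutoff] <- TERNARY_DOWN
  ternary_matrix(out)
}

#' Negate ternary states
#'
#' Swaps up and down states and fixes no-change.
#'
#' @param x A [ternary_matrix()] or integer vector of states.
#' @return Object of the same shape with negated states.
#' @export
negate_ternary <- function(x) {
  out <- -unclass(x)
  if (is_ternary_matrix(x)) out <- ternary_matrix(out)
  out
}

state_to_word <- function(s) {
  names(.ternary_levels)[match(s, .ternary_levels)]
}

word_to_state <- function(w) {
  map <- ternary_tokens()
  out <- map[w]
  if (any(is.na(out))) stop_input(sprintf("unknown ternary token '%s'", w[is.na(out)][1L]))
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
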