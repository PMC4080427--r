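#' Read a time-series expression table
#'
#' Tab-separated text with a header row of time-point labels and a first
#' column of gene/TF identifiers. `dialect = "real"` returns a numeric
#' matrix of log-ratios (feed it to [ternarize()]); `dialect = "ternary"`
#' expects state tokens (by default `+`/`-`/`0` or `up`/`down`/`nc`) and
#' returns a [ternary_matrix()].
#'
#' @param path Path to the TSV file.
#' @param dialect Either `"real"` or `"ternary"`.
#' @param tokens Named integer vector mapping ternary tokens to states;
#'   see [ternary_tokens()].
#' @return Numeric matrix or [ternary_matrix()], rows named by entity id.
#' @export
read_expression <- function(path, dialect = c("real", "ternary"),
                            tokens = ternary_tokens()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_input("expression table '%s' has no data rows", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  # header may or may not carry a leading cell for the id column
  body <- parts[-1L]
  width <- lengths(body)
  if (length(unique(width)) != 1L) {
    bad <- which(width != width[1L])[1L] + 1L
    stop_input("ragged expression table '%s': line %d has %d fields, expected %d",
               path, bad, width[bad - 1L], width[1L])
  }
  ncol_data <- width[1L] - 1L
  time_labels <- if (length(header) == ncol_data) header else header[-1L]
  if (length(time_labels) != ncol_data) {
    stop_input("header of '%s' has %d labels for %d data columns",
               path, length(time_labels), ncol_data)
  }
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_input("duplicate entity id '%s' in '%s'", ids[duplicated(ids)][1L], path)
  }
  cells <- t(vapply(body, function(f) f[-1L], character(ncol_data)))
  if (ncol_data == 1L) cells <- matrix(cells, ncol = 1L)
  dimnames(cells) <- list(ids, time_labels)
  if (dialect == "real") {
    vals <- suppressWarnings(array(as.numeric(cells), dim(cells), dimnames(cells)))
    if (any(is.na(vals))) {
      i <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop_input("non-numeric value '%s' for '%s' in '%s'",
                 cells[i[1L], i[2L]], ids[i[1L]], path)
    }
    return(vals)
  }
  tok <- trimws(cells)
  unknown <- array(!(tok %in% names(tokens)), dim(tok))
  if (any(unknown)) {
    i <- which(unknown, arr.ind = TRUE)[1L, ]
    stop_input("unknown ternary token '%s' at line %d of '%s'",
               tok[i[1L], i[2L]], i[1L] + 1L, path)
  }
  ternary_matrix(array(unname(tokens[tok]), dim(tok), dimnames(tok)))
}

#' Write an expression table
#'
#' @param expr Numeric matrix or [ternary_matrix()].
#' @param path Output TSV path.
#' @param tokens Tokens used to encode ternary states (first token per
#'   state in the map is used).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, tokens = ternary_tokens()) {
  if (is_ternary_matrix(expr)) {
    enc <- names(tokens)[match(c(1L, -1L, 0L), tokens)]
    cells <- array(enc[match(unclass(expr), c(1L, -1L, 0L))], dim(expr), dimnames(expr))
  } else {
    cells <- expr
  }
  df <- data.frame(id = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-DNA binding network
#'
#' Two-column tab-separated edge list (TF id, target id); lines starting
#' with `#` are comments. Duplicate edges are collapsed. A node may appear
#' both as a TF and as a target (TF-on-TF binding is allowed).
#'
#' @param path Path to the edge-list TSV.
#' @return A `binding_network`: data frame with columns `tf`, `gene`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != 2L)) {
    bad <- which(keep)[which(nf != 2L)[1L]]
    stop_input("network '%s': line %d has %d fields, expected 2", path, bad, nf[nf != 2L][1L])
  }
  net <- binding_network(
    tf = vapply(rows, `[[`, "", 1L),
    gene = vapply(rows, `[[`, "", 2L)
  )
  message(sprintf("read binding network: %d TFs, %d targets, %d edges",
                  length(unique(net$tf)), length(unique(net$gene)), nrow(net)))
  net
}

#' Construct a binding network from edge vectors
#'
#' @param tf,gene Character vectors of equal length (one edge per element).
#' @return Deduplicated `binding_network` data frame.
#' @export
binding_network <- function(tf, gene) {
  if (length(tf) != length(gene)) stop_input("tf and gene vectors differ in length")
  df <- unique(data.frame(tf = as.character(tf), gene = as.character(gene),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("binding_network", class(df))
  df
}

#' Write a binding network as a two-column TSV edge list
#' @param net `binding_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net[, c("tf", "gene")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene cluster labels
#'
#' Two-column TSV: gene id, cluster id (header optional, detected by a
#' non-unique... simply: no header expected).
#'
#' @param path Path to TSV.
#' @return Named character vector gene -> cluster id.
#' @export
read_clusters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 2L) stop_input("cluster table '%s' must have 2 columns", path)
  if (anyDuplicated(df[[1L]])) stop_input("duplicate gene id in cluster table '%s'", path)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' Write regulatory modules as TSV
#'
#' Columns: module_id, TF ids joined by `;`, gene ids joined by `;`.
#'
#' @param modules List of regulatory modules (see [build_modules()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_modules <- function(modules, path) {
  df <- as.data.frame(modules)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
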