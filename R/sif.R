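#' Read a network in SIF format
#'
#' Parses the Cytoscape Simple Interaction Format: one interaction per line,
#' `source <sep> interactionType <sep> target [target2 ...]`. A line with k
#' targets creates k edges sharing the label; a single-token line declares an
#' isolated node. Both tab- and space-delimited lines are accepted (Cytoscape
#' accepts both), token-wise, even when mixed within one file. A line with
#' exactly two tokens is malformed and raises a parse error naming the line.
#'
#' SIF itself carries no direction semantics, so directedness is a load-time
#' flag, not inferred from the file.
#'
#' @param file path to a SIF file (or a connection).
#' @param directed treat the edges as directed?
#' @return an [spn_graph()].
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines(c("1 pp 8", "8 pp 7 10"), f)
#' read_sif(f)
#' @export
read_sif <- function(file, directed = FALSE) {
  lines <- tryCatch(readLines(file, warn = FALSE), error = function(e)
    spn_stop("io", sprintf("cannot read network file: %s", conditionMessage(e))))
  from <- character()
  to <- character()
  label <- character()
  singles <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (!length(tok)) next
    if (length(tok) == 1L) {
      singles <- c(singles, tok)
    } else if (length(tok) == 2L) {
      spn_stop("parse", sprintf(
        "malformed SIF line %d: found 2 tokens, need 1 (isolated node) or >= 3 (source label target ...)", i))
    } else {
      k <- length(tok) - 2L
      from <- c(from, rep(tok[1L], k))
      label <- c(label, rep(tok[2L], k))
      to <- c(to, tok[3:length(tok)])
    }
  }
  spn_graph(edges = data.frame(from = from, to = to, label = label,
                               stringsAsFactors = FALSE),
            nodes = singles, directed = directed)
}

#' Write a network in SIF format
#'
#' Emits one `source <tab> label <tab> target` line per edge (canonical
#' stored orientation in undirected mode) plus one single-token line per
#' isolated node, so that reading the file back reproduces the graph model
#' exactly (weights travel separately; see [read_weights()]).
#'
#' @param graph an [spn_graph()].
#' @param file output path (or connection).
#' @return `file`, invisibly.
#' @export
write_sif <- function(graph, file) {
  stopifnot(inherits(graph, "spn_graph"))
  e <- graph$edges
  lines <- if (nrow(e)) paste(e$from, e$label, e$to, sep = "\t") else character()
  iso <- setdiff(graph$nodes, c(e$from, e$to))
  tryCatch(writeLines(c(lines, iso), file), error = function(err)
    spn_stop("io", sprintf("cannot write SIF file: %s", conditionMessage(err))))
  invisible(file)
}
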