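#' Construct a network graph
#'
#' The basic container for every computation in the package: a node set, an
#' edge list with interaction labels, a whole-graph directedness flag, and
#' optional real-valued (possibly negative) edge weights.
#'
#' Invariants enforced by the constructor:
#' * every edge endpoint is a member of the node set; isolated nodes
#'   (mentioned in `nodes` but in no edge) are preserved;
#' * duplicate `(source, target, label)` triples are collapsed to a single
#'   edge; if collapsed duplicates carry different weights the minimum is
#'   kept with a warning (only the cheapest parallel edge can ever lie on a
#'   shortest path);
#' * in undirected mode `(a, b)` and `(b, a)` denote the same edge and are
#'   stored once under a canonical endpoint ordering;
#' * self-loops are stored but ignored by all shortest-path computations.
#'
#' Node identifiers are opaque, case-sensitive strings; no normalization is
#' applied (gene symbols are case-significant).
#'
#' @param edges data frame with character columns `from`, `to` and
#'   optionally `label` (default `"pp"`) and numeric `weight`.
#' @param nodes character vector of additional (possibly isolated) node ids.
#' @param directed logical flag applying to the whole graph.
#' @param weights optional numeric vector parallel to the rows of `edges`;
#'   overrides an existing `weight` column.
#' @return an object of class `spn_graph` with fields `nodes`, `edges`,
#'   `directed`, `weighted`.
#' @examples
#' g <- spn_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' g
#' @export
spn_graph <- function(edges = NULL, nodes = character(), directed = FALSE,
                      weights = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        label = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$label)) edges$label <- rep("pp", nrow(edges))
  for (col in c("from", "to", "label")) edges[[col]] <- as.character(edges[[col]])
  if (!is.null(weights)) {
    if (length(weights) != nrow(edges))
      spn_stop("argument", "weights must have one value per edge")
    edges$weight <- as.numeric(weights)
  }
  weighted <- !is.null(edges$weight)
  if (weighted) edges$weight <- as.numeric(edges$weight)
  if (weighted && anyNA(edges$weight))
    spn_stop("argument", "edge weights must be numeric and non-missing")
  if (nrow(edges) &&
      (anyNA(edges$from) || anyNA(edges$to) ||
       !all(nzchar(edges$from)) || !all(nzchar(edges$to))))
    spn_stop("argument", "edge endpoints must be non-empty strings")
  directed <- isTRUE(directed)

  edges <- edges[, c("from", "to", "label", if (weighted) "weight"), drop = FALSE]
  if (!directed && nrow(edges)) {
    swap <- str_lt(edges$to, edges$from)
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, edges$label, sep = "\t")
    if (anyDuplicated(key)) {
      if (weighted) {
        nuniq <- tapply(edges$weight, key, function(x) length(unique(x)))
        if (any(nuniq > 1L))
          warning("duplicate edges with differing weights collapsed to the minimum weight")
        wmin <- tapply(edges$weight, key, min)
        edges <- edges[!duplicated(key), , drop = FALSE]
        edges$weight <- as.numeric(wmin[paste(edges$from, edges$to, edges$label,
                                              sep = "\t")])
      } else {
        edges <- edges[!duplicated(key), , drop = FALSE]
      }
    }
    edges <- edges[order_c(edges$from, edges$to, edges$label), , drop = FALSE]
    rownames(edges) <- NULL
  }

  nodes <- as.character(nodes)
  if (anyNA(nodes) || !all(nzchar(nodes)))
    spn_stop("argument", "node identifiers must be non-empty strings")
  nodes <- sort_c(unique(c(nodes, edges$from, edges$to)))

  structure(
    list(nodes = nodes, edges = edges, directed = directed, weighted = weighted),
    class = "spn_graph"
  )
}

#' @export
print.spn_graph <- function(x, ...) {
  cat(sprintf("<spn_graph> %s, %s: %d nodes, %d edges\n",
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "unweighted",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Remove one edge from a graph
#'
#' Drops every edge (all interaction labels) between the two endpoints; in
#' undirected mode the endpoint order is immaterial. Useful for perturbation
#' checks such as testing whether an edge is a bridge.
#'
#' @param graph an [spn_graph()].
#' @param from,to endpoint node ids.
#' @return a new `spn_graph`; the node set is unchanged (endpoints may
#'   become isolated).
#' @export
remove_edge <- function(graph, from, to) {
  stopifnot(inherits(graph, "spn_graph"))
  e <- graph$edges
  hit <- (e$from == from & e$to == to)
  if (!graph$directed) hit <- hit | (e$from == to & e$to == from)
  if (!any(hit))
    spn_stop("argument", sprintf("no edge between '%s' and '%s'", from, to))
  spn_graph(edges = e[!hit, , drop = FALSE], nodes = graph$nodes,
            directed = graph$directed)
}

# Nodes reachable from `source` by ignoring weights; direction respected in
# directed mode, optionally reversed for strong-connectivity checks.
reachable_from <- function(graph, source, reverse = FALSE) {
  e <- graph$edges
  from <- e$from
  to <- e$to
  if (reverse) {
    tmp <- from
    from <- to
    to <- tmp
  }
  if (!graph$directed) {
    f2 <- c(from, to)
    to <- c(to, from)
    from <- f2
  }
  seen <- structure(logical(length(graph$nodes)), names = graph$nodes)
  seen[source] <- TRUE
  frontier <- source
  while (length(frontier)) {
    nxt <- unique(to[from %in% frontier])
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  names(seen)[seen]
}
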