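# The three reconstruction tasks. Each returns the path collection
# (spn_pathset) plus the subnetwork extracted as the union of those paths.

new_pathset <- function(listings, mode, graph, truncated,
                        source = NULL, selected = NULL, members = NULL) {
  structure(
    list(paths = listings, mode = mode, directed = graph$directed,
         weighted = graph$weighted, truncated = isTRUE(truncated),
         source = source, selected = selected, members = members),
    class = "spn_pathset"
  )
}

mk_listing <- function(path, source, target) {
  list(source = source, target = target, nodes = path$nodes,
       hops = path$hops, weight = path$weight)
}

#' @export
print.spn_pathset <- function(x, ...) {
  cat(sprintf("<spn_pathset> mode '%s': %d listing(s)%s\n", x$mode,
              length(x$paths), if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Shortest-path tree from a single source
#'
#' Collects every shortest path from `source` to every reachable node (a
#' DAG rather than a literal tree when equal-cost paths exist). The
#' zero-hop self path is never listed. The subnetwork is the union of all
#' listed paths, so its nodes are exactly the nodes reachable from the
#' source.
#'
#' @param graph an [spn_graph()].
#' @param source source node id.
#' @param max_paths per-target enumeration cap, see [enumerate_paths()].
#' @return a list with elements `paths` (an `spn_pathset`) and
#'   `subnetwork` (an `spn_subnetwork`).
#' @export
sp_tree <- function(graph, source, max_paths = 10000L) {
  stopifnot(inherits(graph, "spn_graph"))
  source <- as.character(source)
  dag <- shortest_dag(graph, source)
  listings <- list()
  trunc <- FALSE
  for (t in sort_c(setdiff(names(dag$dist), source))) {
    pl <- enumerate_paths(dag, t, max_paths)
    trunc <- trunc || isTRUE(attr(pl, "truncated"))
    listings <- c(listings, lapply(pl, mk_listing, source = source, target = t))
  }
  ps <- new_pathset(listings, "tree", graph, trunc, source = source)
  sub <- build_subnetwork(graph, ps)
  # the tree is rooted at the source even when nothing else is reachable
  if (!(source %in% sub$graph$nodes)) {
    sub$graph <- spn_graph(edges = sub$graph$edges,
                           nodes = c(sub$graph$nodes, source),
                           directed = graph$directed)
  }
  list(paths = ps, subnetwork = sub)
}

#' Shortest-path cluster connecting a node selection
#'
#' Computes all shortest paths for every pair of the selected nodes and
#' returns their union as a minimal-cost module connecting the selection.
#' In undirected mode every unordered pair with k unique paths contributes
#' 2k direction-annotated listings (the forward paths plus their exact
#' reversals); in directed mode every ordered pair is computed
#' independently.
#'
#' @param graph an [spn_graph()].
#' @param selected character vector of two or more node ids (duplicates
#'   are removed before the two-node rule is applied).
#' @param max_paths per-pair enumeration cap.
#' @return a list with elements `paths` and `subnetwork` as in [sp_tree()].
#' @export
sp_cluster <- function(graph, selected, max_paths = 10000L) {
  stopifnot(inherits(graph, "spn_graph"))
  selected <- sort_c(unique(as.character(selected)))
  unknown <- setdiff(selected, graph$nodes)
  if (length(unknown))
    spn_stop("unknown_node", sprintf("unknown node(s): %s",
                                     paste(unknown, collapse = ", ")))
  if (length(selected) < 2L)
    spn_stop("selection", "select two or more nodes")
  listings <- list()
  trunc <- FALSE
  if (graph$directed) {
    for (s in selected) {
      dag <- shortest_dag(graph, s)
      for (t in setdiff(selected, s)) {
        pl <- enumerate_paths(dag, t, max_paths)
        trunc <- trunc || isTRUE(attr(pl, "truncated"))
        listings <- c(listings, lapply(pl, mk_listing, source = s, target = t))
      }
    }
  } else {
    for (i in seq_len(length(selected) - 1L)) {
      a <- selected[i]
      dag <- shortest_dag(graph, a)
      for (b in selected[(i + 1L):length(selected)]) {
        pl <- enumerate_paths(dag, b, max_paths)
        trunc <- trunc || isTRUE(attr(pl, "truncated"))
        fwd <- lapply(pl, mk_listing, source = a, target = b)
        rev_ <- lapply(pl, function(p)
          list(source = b, target = a, nodes = rev(p$nodes),
               hops = p$hops, weight = p$weight))
        listings <- c(listings, fwd, rev_)
      }
    }
  }
  ps <- new_pathset(listings, "cluster", graph, trunc, selected = selected)
  list(paths = ps, subnetwork = build_subnetwork(graph, ps))
}

#' Connect an isolated node to the nearest members of a node set
#'
#' The target set is treated as a single target: with `d*` the minimum
#' shortest-path distance from `source` to any member, the result contains,
#' for every member at distance `d*`, every shortest path from the source
#' to it whose interior nodes contain no member of the set. Members farther
#' than `d*`, and members reachable only through other members, contribute
#' no paths. The members themselves need not share any links.
#'
#' @param graph an [spn_graph()].
#' @param source the node to connect; must not belong to `target_set`.
#' @param target_set non-empty character vector of member node ids.
#' @param max_paths per-member enumeration cap.
#' @return a list with elements `paths` and `subnetwork` as in [sp_tree()].
#' @export
connect_isolated <- function(graph, source, target_set, max_paths = 10000L) {
  stopifnot(inherits(graph, "spn_graph"))
  source <- as.character(source)
  members <- sort_c(unique(as.character(target_set)))
  if (!length(members))
    spn_stop("selection", "the target set must contain at least one node")
  if (source %in% members)
    spn_stop("invalid_selection",
             sprintf("source node '%s' is part of the target set", source))
  unknown <- setdiff(c(source, members), graph$nodes)
  if (length(unknown))
    spn_stop("unknown_node", sprintf("unknown node(s): %s",
                                     paste(unknown, collapse = ", ")))
  dag <- shortest_dag(graph, source)
  reach <- members[members %in% names(dag$dist)]
  if (!length(reach))
    spn_stop("disconnected", sprintf(
      "no member of the target set is reachable from '%s'", source))
  d <- dag$dist[reach]
  dstar <- min(d)
  nearest <- reach[d <= dstar + dag$tol]
  listings <- list()
  trunc <- FALSE
  for (m in nearest) {
    pl <- enumerate_paths(dag, m, max_paths)
    trunc <- trunc || isTRUE(attr(pl, "truncated"))
    keep <- vapply(pl, function(p) {
      interior <- p$nodes[-c(1L, length(p$nodes))]
      !any(interior %in% members)
    }, logical(1))
    listings <- c(listings, lapply(pl[keep], mk_listing, source = source,
                                   target = m))
  }
  ps <- new_pathset(listings, "connect", graph, trunc,
                    source = source, members = members)
  list(paths = ps, subnetwork = build_subnetwork(graph, ps))
}

#' Extract the subnetwork spanned by a path collection
#'
#' The subnetwork's node set is the union of all path nodes and its edge
#' set is the union of all consecutive-pair edges (every matching
#' interaction label between a pair is retained); every node and edge lies
#' on at least one path of the generating collection. Edge weights are
#' carried over from the parent graph, which is kept as a reference.
#'
#' @param graph the parent [spn_graph()].
#' @param paths an `spn_pathset` whose paths all lie in `graph`.
#' @return an object of class `spn_subnetwork` with fields `graph` (the
#'   extracted `spn_graph`) and `parent`.
#' @export
build_subnetwork <- function(graph, paths) {
  stopifnot(inherits(graph, "spn_graph"), inherits(paths, "spn_pathset"))
  e <- graph$edges
  ekey <- paste(e$from, e$to, sep = "\t")
  rows <- integer()
  nodeset <- character()
  for (l in paths$paths) {
    nodes <- l$nodes
    bad <- setdiff(nodes, graph$nodes)
    if (length(bad))
      spn_stop("integrity", sprintf("path references unknown node(s): %s",
                                    paste(bad, collapse = ", ")))
    nodeset <- c(nodeset, nodes)
    if (length(nodes) < 2L) next
    a <- nodes[-length(nodes)]
    b <- nodes[-1L]
    if (!graph$directed) {
      sw <- str_lt(b, a)
      tmp <- a[sw]
      a[sw] <- b[sw]
      b[sw] <- tmp
    }
    qk <- paste(a, b, sep = "\t")
    miss <- setdiff(qk, ekey)
    if (length(miss))
      spn_stop("integrity", sprintf("path uses edge(s) absent from the graph: %s",
                                    paste(gsub("\t", " - ", miss), collapse = ", ")))
    rows <- c(rows, which(ekey %in% qk))
  }
  rows <- sort(unique(rows))
  sub <- spn_graph(edges = e[rows, , drop = FALSE],
                   nodes = sort_c(unique(nodeset)),
                   directed = graph$directed)
  structure(list(graph = sub, parent = graph), class = "spn_subnetwork")
}

#' @export
print.spn_subnetwork <- function(x, ...) {
  cat(sprintf("<spn_subnetwork> %d of %d nodes, %d of %d edges\n",
              length(x$graph$nodes), length(x$parent$nodes),
              nrow(x$graph$edges), nrow(x$parent$edges)))
  invisible(x)
}
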