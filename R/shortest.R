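# All-shortest-paths core: single-source distances (Dijkstra for
# non-negative weights, Bellman-Ford when any weight is negative), the
# predecessor DAG recording every predecessor on at least one shortest
# path, and exhaustive enumeration of the shortest paths it encodes.

# Directed adjacency arrays, self-loops dropped (a self-loop can never lie
# on a simple shortest path), parallel edges collapsed to the minimum
# weight, undirected edges expanded in both directions. Unit weights when
# the graph is unweighted.
build_adj <- function(graph) {
  e <- graph$edges
  w <- if (graph$weighted) e$weight else rep(1, nrow(e))
  keep <- e$from != e$to
  from <- e$from[keep]
  to <- e$to[keep]
  w <- w[keep]
  if (!graph$directed) {
    from2 <- c(from, to)
    to <- c(to, from)
    from <- from2
    w <- c(w, w)
  }
  if (length(from)) {
    o <- order_c(from, to, w)
    from <- from[o]
    to <- to[o]
    w <- w[o]
    keep2 <- !duplicated(paste(from, to, sep = "\t"))
    from <- from[keep2]
    to <- to[keep2]
    w <- w[keep2]
  }
  idx <- split(seq_along(from), factor(from, levels = graph$nodes))
  stats::setNames(
    lapply(idx, function(ix) list(to = to[ix], w = w[ix])),
    graph$nodes
  )
}

# Plain array Dijkstra; deterministic (nodes scanned in sorted order, ties
# broken by that order, which cannot affect the final distances).
dijkstra_dist <- function(nodes, adj, source) {
  dist <- structure(rep(Inf, length(nodes)), names = nodes)
  dist[source] <- 0
  done <- structure(logical(length(nodes)), names = nodes)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- names(cand)[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (length(nb$to)) {
      better <- dist[u] + nb$w < dist[nb$to]
      dist[nb$to[better]] <- dist[u] + nb$w[better]
    }
  }
  dist
}

# Bellman-Ford over the expanded edge list; raises a classed error naming
# one cycle when a negative-total-weight cycle is reachable from the source.
bellman_ford_dist <- function(nodes, adj, source) {
  from <- rep(names(adj), vapply(adj, function(a) length(a$to), 0L))
  to <- unlist(lapply(adj, `[[`, "to"), use.names = FALSE)
  w <- unlist(lapply(adj, `[[`, "w"), use.names = FALSE)
  dist <- structure(rep(Inf, length(nodes)), names = nodes)
  parent <- structure(rep(NA_character_, length(nodes)), names = nodes)
  dist[source] <- 0
  n <- length(nodes)
  if (n > 1L && length(from)) {
    for (round in seq_len(n - 1L)) {
      changed <- FALSE
      for (i in seq_along(from)) {
        df <- dist[[from[i]]]
        if (is.finite(df) && df + w[i] < dist[[to[i]]] - SPN_TOL) {
          dist[[to[i]]] <- df + w[i]
          parent[[to[i]]] <- from[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    cand <- dist[from] + w
    bad <- which(is.finite(cand) & cand < dist[to] - SPN_TOL)
    if (length(bad)) {
      # a still-improving edge proves a reachable negative cycle; follow
      # parent pointers from its head until a node repeats to name one
      for (b in bad) {
        parent[[to[b]]] <- from[b]
        x <- to[b]
        seen <- character()
        while (!is.na(x) && !(x %in% seen)) {
          seen <- c(seen, x)
          x <- unname(parent[x])
        }
        if (!is.na(x)) {
          cyc <- rev(seen[match(x, seen):length(seen)])
          spn_stop("negative_cycle", sprintf(
            "negative-weight cycle reachable from '%s': %s",
            source, paste(c(cyc, cyc[1L]), collapse = " -> ")))
        }
      }
      spn_stop("negative_cycle", sprintf(
        "negative-weight cycle reachable from '%s'", source))
    }
  }
  dist
}

# Derive the predecessor sets from the converged distances: u is a
# predecessor of v iff dist[u] + w(u,v) = dist[v] (exact when unweighted,
# within tolerance in weighted mode). This realizes the usual
# all-shortest-paths relaxation rule (strictly better replaces, equal
# adds) as a single deterministic pass. Degenerate zero-total-weight
# cycles inside the shortest-path subgraph make "all shortest paths"
# infinite, so they are detected and rejected.
derive_preds <- function(nodes, adj, dist, source, tol) {
  reach <- names(dist)[is.finite(dist)]
  preds <- stats::setNames(vector("list", length(reach)), reach)
  for (v in reach) preds[[v]] <- character()
  for (u in reach) {
    nb <- adj[[u]]
    if (!length(nb$to)) next
    ok <- abs(dist[u] + nb$w - dist[nb$to]) <= tol
    for (v in nb$to[ok]) {
      if (v == source) {
        spn_stop("degenerate_cycle", sprintf(
          "zero-total-weight cycle through source '%s' (via '%s'): all shortest paths would be unbounded",
          source, u))
      }
      preds[[v]] <- c(preds[[v]], u)
    }
  }
  preds <- lapply(preds, sort_c)
  preds[[source]] <- character()

  # Kahn topological check over the predecessor relation
  indeg <- vapply(preds, length, 0L)
  queue <- names(indeg)[indeg == 0L]
  succ <- invert_preds(preds)
  seen <- 0L
  while (length(queue)) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (v in succ[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  if (seen < length(preds)) {
    start <- names(indeg)[indeg > 0L][1L]
    cyc <- start
    x <- start
    repeat {
      x <- preds[[x]][preds[[x]] %in% names(indeg)[indeg > 0L]][1L]
      if (x %in% cyc) {
        cyc <- c(cyc[which(cyc == x):length(cyc)], x)
        break
      }
      cyc <- c(cyc, x)
    }
    spn_stop("degenerate_cycle", sprintf(
      "zero-total-weight cycle on a shortest path: %s",
      paste(rev(cyc), collapse = " -> ")))
  }
  preds
}

invert_preds <- function(preds) {
  succ <- stats::setNames(vector("list", length(preds)), names(preds))
  for (v in names(succ)) succ[[v]] <- character()
  for (v in names(preds)) for (p in preds[[v]]) succ[[p]] <- c(succ[[p]], v)
  lapply(succ, sort_c)
}

#' Single-source all-shortest-paths predecessor DAG
#'
#' Computes, for one source node, the shortest-path distance to every
#' reachable node together with, for each node, the set of *all*
#' predecessors lying on at least one shortest path. This predecessor DAG
#' compactly encodes every shortest path from the source and is the input
#' to [enumerate_paths()].
#'
#' Unweighted graphs use unit edge weights. With non-negative weights the
#' distances come from Dijkstra's algorithm; as soon as any edge weight is
#' negative the Bellman-Ford branch is used instead (Dijkstra is incorrect
#' under negative weights). A negative-total-weight cycle reachable from
#' the source raises an error naming one such cycle; a zero-total-weight
#' cycle lying on a shortest path raises a degenerate-cycle error, because
#' the set of all (simple) shortest paths is not well defined there.
#'
#' Distance ties are detected exactly in unweighted mode and within an
#' absolute tolerance of 1e-9 in weighted mode.
#'
#' @param graph an [spn_graph()].
#' @param source source node id; must belong to the graph.
#' @param method `"auto"` (default: Dijkstra unless a negative weight is
#'   present), or force `"dijkstra"` / `"bellman_ford"`. Forcing Dijkstra
#'   on a negative-weight graph is an error.
#' @return an object of class `spn_dag` with fields `source`, `dist`
#'   (named numeric over reachable nodes), `preds` (named list of sorted
#'   predecessor vectors), `weighted` and `tol`.
#' @examples
#' g <- read_sif(textConnection("A pp B\nB pp C"))
#' shortest_dag(g, "A")$dist
#' @export
shortest_dag <- function(graph, source,
                         method = c("auto", "dijkstra", "bellman_ford")) {
  stopifnot(inherits(graph, "spn_graph"))
  method <- match.arg(method)
  source <- as.character(source)
  if (length(source) != 1L || !(source %in% graph$nodes))
    spn_stop("unknown_node", sprintf("unknown node '%s'", source))
  has_neg <- graph$weighted && nrow(graph$edges) && any(graph$edges$weight < 0)
  if (method == "auto") method <- if (has_neg) "bellman_ford" else "dijkstra"
  if (method == "dijkstra" && has_neg)
    spn_stop("argument", "Dijkstra cannot be used on graphs with negative weights")
  adj <- build_adj(graph)
  dist <- if (method == "bellman_ford") {
    bellman_ford_dist(graph$nodes, adj, source)
  } else {
    dijkstra_dist(graph$nodes, adj, source)
  }
  tol <- spn_tol(graph$weighted)
  preds <- derive_preds(graph$nodes, adj, dist, source, tol)
  reach <- sort_c(names(dist)[is.finite(dist)])
  structure(
    list(source = source,
         dist = dist[reach],
         preds = preds[reach],
         weighted = graph$weighted,
         tol = tol),
    class = "spn_dag"
  )
}

#' @export
print.spn_dag <- function(x, ...) {
  cat(sprintf("<spn_dag> source '%s': %d reachable node(s)\n",
              x$source, length(x$dist)))
  invisible(x)
}

#' Enumerate every shortest path to a target
#'
#' Expands the predecessor DAG of [shortest_dag()] into the full list of
#' distinct shortest paths from its source to `target`. Paths are simple
#' (the predecessor relation is acyclic by construction) and are emitted in
#' deterministic lexicographic order of their node sequences. An
#' unreachable target yields an empty list (not an error); `target` equal
#' to the source yields the single zero-hop path.
#'
#' The number of shortest paths can grow exponentially, so enumeration
#' stops at `max_paths`; when paths were dropped the `truncated` attribute
#' of the result is `TRUE`. Because the emission order is lexicographic,
#' truncation is reproducible.
#'
#' @param dag an `spn_dag` from [shortest_dag()].
#' @param target target node id.
#' @param max_paths positive integer cap on the number of returned paths.
#' @return a list of paths, each a list with fields `nodes` (node-id
#'   sequence), `hops` (edge count) and `weight` (total cost, equal to
#'   `hops` in unweighted mode), with attribute `truncated`.
#' @export
enumerate_paths <- function(dag, target, max_paths = 10000L) {
  stopifnot(inherits(dag, "spn_dag"))
  target <- as.character(target)
  if (!is.numeric(max_paths) || length(max_paths) != 1L || max_paths < 1)
    spn_stop("argument", "max_paths must be a positive integer")
  max_paths <- as.integer(max_paths)
  if (!(target %in% names(dag$dist)))
    return(structure(list(), truncated = FALSE))

  # nodes lying on at least one source -> target shortest path
  onpath <- character()
  stack <- target
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v %in% onpath) next
    onpath <- c(onpath, v)
    stack <- c(stack, dag$preds[[v]])
  }
  succ <- new.env(parent = emptyenv())
  for (v in onpath) assign(v, character(), envir = succ)
  for (v in onpath) {
    for (p in dag$preds[[v]]) assign(p, c(get(p, envir = succ), v), envir = succ)
  }
  for (v in onpath) assign(v, sort_c(get(v, envir = succ)), envir = succ)

  state <- new.env(parent = emptyenv())
  state$out <- vector("list", min(max_paths, 64L))
  state$n <- 0L
  state$truncated <- FALSE
  walk <- function(node, acc) {
    if (state$truncated) return(invisible())
    acc <- c(acc, node)
    if (node == target) {
      if (state$n >= max_paths) {
        state$truncated <- TRUE
      } else {
        state$n <- state$n + 1L
        if (state$n > length(state$out))
          length(state$out) <- 2L * length(state$out)
        state$out[[state$n]] <- acc
      }
      return(invisible())
    }
    for (s in get(node, envir = succ)) walk(s, acc)
    invisible()
  }
  walk(dag$source, character())

  wt <- unname(dag$dist[target])
  paths <- lapply(state$out[seq_len(state$n)], function(nodes)
    list(nodes = nodes, hops = length(nodes) - 1L, weight = wt))
  structure(paths, truncated = state$truncated)
}

#' All-pairs shortest paths
#'
#' Runs [shortest_dag()] from every node and enumerates the shortest paths
#' for every ordered pair (including the zero-hop self path for each
#' node). In undirected mode the two orderings of an unordered pair each
#' yield a listing, the second being the node-by-node reversal of the
#' first (matching the two-directional display of results for one pair).
#'
#' @param graph an [spn_graph()].
#' @param max_paths_per_pair cap on enumerated paths per ordered pair.
#' @return a named list keyed `"<source>\t<target>"`, each element the
#'   path list of [enumerate_paths()] (empty for unreachable pairs), with
#'   attribute `truncated` set if any pair hit the cap.
#' @export
all_pairs <- function(graph, max_paths_per_pair = 10000L) {
  stopifnot(inherits(graph, "spn_graph"))
  res <- list()
  trunc <- FALSE
  for (s in graph$nodes) {
    dag <- shortest_dag(graph, s)
    for (t in graph$nodes) {
      pl <- enumerate_paths(dag, t, max_paths_per_pair)
      if (isTRUE(attr(pl, "truncated"))) trunc <- TRUE
      res[[paste(s, t, sep = "\t")]] <- pl
    }
  }
  structure(res, truncated = trunc)
}
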