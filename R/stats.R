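# Results-panel statistics: paths grouped by size, average path length,
# unique and expected path counts, and the Connected flag.

# Indices of the unique paths of a path set. In undirected mode a forward
# listing and its reversal describe the same path and count once; the
# canonical key is the lexicographically smaller of the two node-sequence
# renderings.
unique_path_index <- function(pathset) {
  if (!length(pathset$paths)) return(integer())
  keys <- vapply(pathset$paths, function(l) {
    k <- paste(l$nodes, collapse = "|")
    if (!pathset$directed) {
      kr <- paste(rev(l$nodes), collapse = "|")
      k <- sort_c(c(k, kr))[1L]
    }
    k
  }, character(1))
  which(!duplicated(keys))
}

path_sizes <- function(pathset, idx) {
  vapply(pathset$paths[idx], function(l)
    if (pathset$weighted) l$weight else as.numeric(l$hops), numeric(1))
}

#' Group shortest paths by size
#'
#' Tabulates how many *unique* paths have each size, where size is the hop
#' count (or the total weight in weighted mode, since that is the
#' optimized quantity). In undirected mode a forward/reverse listing pair
#' counts as one path.
#'
#' @param pathset an `spn_pathset` from one of the task functions.
#' @return a data frame of class `spn_lengthtable` with columns `size` and
#'   `count`, sorted by size; its counts sum to the unique-path count.
#' @export
group_by_length <- function(pathset) {
  stopifnot(inherits(pathset, "spn_pathset"))
  idx <- unique_path_index(pathset)
  sizes <- path_sizes(pathset, idx)
  u <- sort(unique(sizes))
  count <- vapply(u, function(s) sum(sizes == s), integer(1))
  structure(data.frame(size = u, count = count),
            class = c("spn_lengthtable", "data.frame"))
}

#' Summary statistics for a task result
#'
#' The four bottom-table values of a run: the average path length (mean
#' size over unique paths; `NA` when there are none), the number of unique
#' shortest paths, the number of expected paths (see [expected_paths()];
#' `NA` for the connect task, where the notion does not apply), and the
#' Connected flag — reachability of every node from the source for
#' source-rooted tasks, global connectivity for the cluster task.
#'
#' @param pathset an `spn_pathset`.
#' @param graph the graph the task ran on.
#' @return an object of class `spn_stats` with fields
#'   `average_path_length`, `unique_paths`, `expected_paths`, `connected`.
#' @export
compute_stats <- function(pathset, graph) {
  stopifnot(inherits(pathset, "spn_pathset"), inherits(graph, "spn_graph"))
  idx <- unique_path_index(pathset)
  sizes <- path_sizes(pathset, idx)
  avg <- if (length(idx)) mean(sizes) else NA_real_
  expected <- switch(pathset$mode,
    tree = expected_paths(graph, "tree", length(graph$nodes)),
    cluster = expected_paths(graph, "cluster", length(pathset$selected)),
    connect = NA_integer_)
  connected <- switch(pathset$mode,
    cluster = is_connected(graph, "global"),
    is_connected(graph, "from_source", pathset$source))
  structure(
    list(average_path_length = avg, unique_paths = length(idx),
         expected_paths = expected, connected = connected),
    class = "spn_stats"
  )
}

#' @export
print.spn_stats <- function(x, ...) {
  cat(sprintf("average path length : %s\n",
              if (is.na(x$average_path_length)) "NA"
              else format(x$average_path_length)))
  cat(sprintf("unique paths        : %d\n", x$unique_paths))
  cat(sprintf("expected paths      : %s\n",
              if (is.na(x$expected_paths)) "NA" else x$expected_paths))
  cat(sprintf("connected           : %s\n",
              if (is.na(x$connected)) "NA" else if (x$connected) "True" else "False"))
  invisible(x)
}

#' Connectivity of a graph
#'
#' `global` mode asks whether all nodes can communicate by paths: a single
#' connected component for undirected graphs, strong connectivity for
#' directed ones. `from_source` mode asks whether every other node is
#' reachable from `source` (direction respected in directed mode) — the
#' flag reported for single-source runs.
#'
#' @param graph an [spn_graph()].
#' @param mode `"global"` or `"from_source"`.
#' @param source required in `from_source` mode.
#' @return a single logical.
#' @export
is_connected <- function(graph, mode = c("global", "from_source"),
                         source = NULL) {
  stopifnot(inherits(graph, "spn_graph"))
  mode <- match.arg(mode)
  n <- length(graph$nodes)
  if (mode == "from_source") {
    if (is.null(source))
      spn_stop("argument", "from_source connectivity requires a source node")
    source <- as.character(source)
    if (!(source %in% graph$nodes))
      spn_stop("unknown_node", sprintf("unknown node '%s'", source))
    return(length(reachable_from(graph, source)) == n)
  }
  if (n <= 1L) return(TRUE)
  root <- graph$nodes[1L]
  if (!graph$directed) return(length(reachable_from(graph, root)) == n)
  length(reachable_from(graph, root)) == n &&
    length(reachable_from(graph, root, reverse = TRUE)) == n
}

#' Expected number of shortest-path relations
#'
#' The total number of path relations a fully connected network would
#' exhibit among the relevant nodes: `n - 1` source-to-target relations
#' for a single-source tree, one per unordered pair (`n(n-1)/2`) for an
#' undirected cluster, one per ordered pair (`n(n-1)`) for a directed
#' cluster. Realized unique paths are compared against this denominator.
#'
#' @param graph an [spn_graph()] (supplies directedness).
#' @param paths_mode `"tree"` or `"cluster"`.
#' @param n_relevant node count (tree) or selection size (cluster); must
#'   be a positive integer.
#' @return a single integer.
#' @export
expected_paths <- function(graph, paths_mode = c("tree", "cluster"),
                           n_relevant) {
  stopifnot(inherits(graph, "spn_graph"))
  paths_mode <- match.arg(paths_mode)
  if (!is.numeric(n_relevant) || length(n_relevant) != 1L ||
      is.na(n_relevant) || n_relevant < 1)
    spn_stop("argument", "n_relevant must be a positive integer")
  n <- as.integer(n_relevant)
  if (paths_mode == "tree") return(n - 1L)
  if (graph$directed) n * (n - 1L) else as.integer(n * (n - 1L) / 2)
}
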