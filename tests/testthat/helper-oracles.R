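# Independent test oracles: exhaustive DFS over all simple paths filtered
# to minimum total weight, and a matrix Floyd-Warshall for distances.
# They read only the graph's data fields and share no code with the
# package's shortest-path implementation.

oracle_adj <- function(graph) {
  e <- graph$edges
  e <- e[e$from != e$to, , drop = FALSE]
  w <- if (!is.null(e$weight)) e$weight else rep(1, nrow(e))
  from <- e$from
  to <- e$to
  if (!graph$directed) {
    from <- c(from, e$to)
    to <- c(to, e$from)
    w <- c(w, w)
  }
  # collapse parallel edges to the minimum weight
  key <- paste(from, to, sep = "\t")
  o <- order(key, w, method = "radix")
  from <- from[o]; to <- to[o]; w <- w[o]; key <- key[o]
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]; w <- w[keep]
  adj <- lapply(split(seq_along(from), factor(from, levels = graph$nodes)),
                function(ix) list(to = to[ix], w = w[ix]))
  names(adj) <- graph$nodes
  adj
}

# All minimum-weight simple paths s -> t, as a lexicographically sorted
# list of node-id vectors. Empty list when unreachable; list(s) when s == t.
brute_force_paths <- function(graph, s, t) {
  if (s == t) return(list(s))
  adj <- oracle_adj(graph)
  found <- list()
  dfs <- function(node, acc, wsum) {
    nb <- adj[[node]]
    for (i in seq_along(nb$to)) {
      v <- nb$to[i]
      if (v %in% acc) next
      if (v == t) {
        found[[length(found) + 1L]] <<- list(nodes = c(acc, v), w = wsum + nb$w[i])
      } else {
        dfs(v, c(acc, v), wsum + nb$w[i])
      }
    }
  }
  dfs(s, s, 0)
  if (!length(found)) return(list())
  ws <- vapply(found, `[[`, numeric(1), "w")
  keep <- ws <= min(ws) + 1e-9
  paths <- lapply(found[keep], `[[`, "nodes")
  # tab-joined radix order equals element-wise lexicographic order of the
  # node sequences (tab sorts below every printable id character)
  paths[order(vapply(paths, paste, character(1), collapse = "\t"),
              method = "radix")]
}

# Distance matrix by Floyd-Warshall over the adjacency matrix.
fw_dist <- function(graph) {
  n <- length(graph$nodes)
  D <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  diag(D) <- 0
  adj <- oracle_adj(graph)
  for (u in graph$nodes) {
    nb <- adj[[u]]
    for (i in seq_along(nb$to)) D[u, nb$to[i]] <- min(D[u, nb$to[i]], nb$w[i])
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Package-side path list for one pair, as sorted node-id vectors, for
# direct comparison with brute_force_paths().
pkg_pair_paths <- function(graph, s, t, max_paths = 100000L) {
  pl <- enumerate_paths(shortest_dag(graph, s), t, max_paths)
  lapply(pl, `[[`, "nodes")
}

# A seeded random tree on n nodes (every edge a bridge); test-local RNG.
make_tree <- function(n, seed) {
  set.seed(seed)
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  spn_graph(edges = data.frame(from = paste0("n", parent),
                               to = paste0("n", 2:n),
                               stringsAsFactors = FALSE))
}

# Elementwise "a <= b" under byte collation (locale-independent).
str_pair_le <- function(a, b) {
  u <- sort(unique(c(a, b)), method = "radix")
  match(a, u) <= match(b, u)
}

# Standard sweep of seeded random-graph configurations.
oracle_grid <- function(n_seeds) {
  grid <- expand.grid(directed = c(FALSE, TRUE), weighted = c(FALSE, TRUE),
                      seed = seq_len(n_seeds))
  grid$n <- 2L + (grid$seed + seq_len(nrow(grid))) %% 9L
  grid
}
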