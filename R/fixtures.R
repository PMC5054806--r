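# Bundled example networks and the seeded random-graph generator that
# powers the oracle-based tests.

spn_extdata <- function(name) {
  p <- system.file("extdata", name, package = "sprecon")
  if (!nzchar(p)) spn_stop("io", sprintf("bundled network '%s' not found", name))
  p
}

#' Example network: undirected cluster demo
#'
#' A small undirected network of ten numbered nodes and fourteen edges
#' used throughout the documentation and tests. Its key property: nodes 1
#' and 9 are joined by exactly two shortest paths of four hops each,
#' `1-8-7-4-9` and `1-8-10-4-9`, and the network is globally connected
#' (edge `4-9` is a bridge whose removal disconnects node 9).
#'
#' @return an undirected [spn_graph()] with 10 nodes and 14 edges.
#' @export
toy_cluster_network <- function() {
  read_sif(spn_extdata("toy_cluster.sif"), directed = FALSE)
}

#' Example network: directed reachability demo
#'
#' A small directed network with non-communicating nodes: every node is
#' reachable from node 1, but node 1 is unreachable from nodes 2 and 3,
#' so the single-source Connected flag is `TRUE` only from node 1.
#'
#' @return a directed [spn_graph()].
#' @export
toy_directed_network <- function() {
  read_sif(spn_extdata("toy_directed.sif"), directed = TRUE)
}

#' Example network: isolated-node attachment demo
#'
#' An undirected network of ten nodes and fourteen edges in which node 6
#' sits at distance two from members 8 and 10 of the set `{8, 9, 10}`
#' while member 9, reachable only through 8 or 10, lies farther away:
#' [connect_isolated()] therefore returns exactly two paths, one ending
#' at 8 and one at 10, and none ending at 9.
#'
#' @return an undirected [spn_graph()] with 10 nodes and 14 edges.
#' @export
toy_connect_network <- function() {
  read_sif(spn_extdata("toy_connect.sif"), directed = FALSE)
}

# Park-Miller "minimal standard" linear congruential generator
# (x <- 48271 * x mod (2^31 - 1)), exact in double arithmetic, used instead
# of the platform RNG so that seeded graphs are bit-reproducible across
# platforms and R versions.
lcg_init <- function(seed) {
  s <- suppressWarnings(as.numeric(seed))
  if (length(s) != 1L || !is.finite(s))
    spn_stop("argument", "seed must be a single finite integer")
  e <- new.env(parent = emptyenv())
  e$state <- (abs(floor(s)) %% 2147483646) + 1
  # warm-up: nearby raw seeds give correlated first outputs (the state is
  # linear in the seed), so discard a fixed number of draws before use
  for (i in 1:16) lcg_next(e)
  e
}

lcg_next <- function(rng) {
  rng$state <- (48271 * rng$state) %% 2147483647
  rng$state / 2147483647
}

#' Seeded Erdős–Rényi random graph
#'
#' Generates a G(n, p) graph with reproducible structure: identical
#' arguments (including the seed) give an identical graph on every
#' platform, because the randomness comes from a fixed Park-Miller linear
#' congruential generator rather than the platform RNG. Each (ordered, in
#' directed mode; unordered otherwise) node pair receives an edge with
#' probability `edge_prob`; optional weights are drawn uniformly from
#' `weight_range`.
#'
#' @param n number of nodes (`n >= 1`); isolated nodes are kept.
#' @param edge_prob edge probability in (0, 1].
#' @param directed generate a directed graph?
#' @param weighted attach uniform random weights?
#' @param weight_range length-2 numeric, lower and upper weight bound
#'   (negative values allowed).
#' @param seed integer seed.
#' @return an [spn_graph()] with nodes `n1 ... n<n>`.
#' @examples
#' random_graph(6, 0.4, seed = 1)
#' @export
random_graph <- function(n, edge_prob, directed = FALSE, weighted = FALSE,
                         weight_range = c(0.5, 2), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    spn_stop("argument", "n must be a positive integer")
  n <- as.integer(n)
  if (!is.numeric(edge_prob) || length(edge_prob) != 1L ||
      is.na(edge_prob) || edge_prob <= 0 || edge_prob > 1)
    spn_stop("argument", "edge_prob must lie in (0, 1]")
  if (!is.numeric(weight_range) || length(weight_range) != 2L ||
      anyNA(weight_range) || !all(is.finite(weight_range)) ||
      weight_range[1L] > weight_range[2L])
    spn_stop("argument", "weight_range must be a finite, ordered length-2 numeric")
  rng <- lcg_init(seed)
  nodes <- paste0("n", seq_len(n))
  from <- character()
  to <- character()
  if (n > 1L) {
    for (i in seq_len(n)) {
      js <- if (directed) setdiff(seq_len(n), i) else if (i < n) (i + 1L):n else integer()
      for (j in js) {
        if (lcg_next(rng) < edge_prob) {
          from <- c(from, nodes[i])
          to <- c(to, nodes[j])
        }
      }
    }
  }
  w <- if (weighted) {
    vapply(seq_along(from), function(k)
      weight_range[1L] + lcg_next(rng) * (weight_range[2L] - weight_range[1L]),
      numeric(1))
  } else NULL
  spn_graph(edges = data.frame(from = from, to = to,
                               label = rep("pp", length(from)),
                               stringsAsFactors = FALSE),
            nodes = nodes, directed = directed, weights = w)
}
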