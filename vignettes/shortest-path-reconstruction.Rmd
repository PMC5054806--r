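---
title: "Reconstructing subnetworks from all shortest paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing subnetworks from all shortest paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprecon)
```

## The problem

In systems biology it is common to assume that information flow through an
interactome follows a maximum-parsimony route: the biologically relevant
connection between two genes or proteins is a shortest path in the
interaction network. A single shortest path, however, is rarely unique —
interactomes are dense and ties are the norm — so any reconstruction method
that returns one arbitrary representative biases the result. `sprecon`
therefore enumerates *every* shortest path between the node pairs of
interest and builds subnetworks as the union of those paths.

Three reconstruction tasks are offered:

* **`sp_tree(graph, source)`** — all shortest paths from one source to every
  reachable node. Because ties are kept, the result is in general a DAG
  rather than a literal tree.
* **`sp_cluster(graph, selected)`** — all shortest paths between every pair
  of two or more selected nodes; the union is a minimal-cost module
  connecting the selection.
* **`connect_isolated(graph, source, target_set)`** — attaches a node of
  interest to the *nearest* members of a node set (the set need not be
  internally connected).

Each task returns the path collection (`spn_pathset`) and the extracted
subnetwork, and `compute_stats()` / `group_by_length()` reproduce the
classic results-panel statistics: the by-size path table, the average path
length, the number of unique and expected paths, and the Connected flag.

## The model and its core algorithm

Graphs are node sets plus labelled edge lists (Cytoscape SIF format), with
a whole-graph directedness flag and optional real edge weights, which may
be negative. Unweighted edges count one hop each.

For a fixed source $s$, the package computes the distance $d(v)$ of every
node and the **predecessor DAG**: for each node $v$, the set

$$\mathrm{preds}(v) \;=\; \{\, u : d(u) + w(u,v) = d(v) \,\}$$

of neighbours lying on at least one shortest path from $s$. This relation
is the compact encoding of *all* shortest paths: every path from $s$ to
$t$ obtained by walking predecessor links backwards from $t$ is shortest,
and every shortest path arises this way. `enumerate_paths()` expands the
DAG by a depth-first traversal over its forward (successor) relation
restricted to the nodes that can still reach the target, so paths are
emitted in lexicographic order of their node sequences — a total,
platform-independent order that makes outputs byte-reproducible.

Distances come from Dijkstra's algorithm when all weights are
non-negative and from Bellman–Ford as soon as any weight is negative
(Dijkstra's greedy invariant breaks under negative weights). Both
branches feed the same predecessor derivation, so they produce identical
DAGs wherever both are applicable — a property the test suite asserts on
seeded random graphs.

### Degenerate inputs

* **Negative cycles.** A negative-total-weight cycle reachable from the
  source makes "shortest" meaningless; Bellman–Ford detects it and the
  package raises an error naming one offending cycle. Note that in an
  *undirected* graph every negative edge is itself a two-edge negative
  cycle, so negative weights are effectively a directed-graph feature.
* **Zero-weight cycles.** A zero-total-weight cycle lying on a shortest
  path would make the set of all shortest paths infinite (every extra lap
  costs nothing). The predecessor relation is checked for acyclicity and a
  degenerate-cycle error is raised instead of enumerating unbounded walks;
  paths are defined to be simple.
* **Self-loops** are parsed and stored but ignored by all shortest-path
  computations: with positive weights they can never lie on a shortest
  path, and otherwise they only create the pathologies above.
* **Unreachable targets** are a valid empty result, never an error; they
  are simply absent from the distance map.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_paths` | 10 000 | cap on enumerated paths per pair (unitless count). Path counts grow exponentially with tied diamonds, so enumeration truncates deterministically (lexicographic prefix) and sets a `truncated` flag that the CLI surfaces — silent truncation would corrupt the statistics. |
| tie tolerance | 1e-9 (absolute) | two weighted distances within this tolerance are tied, hence both predecessors are kept. Exact comparison is used in unweighted mode. A fixed absolute tolerance keeps tie detection reproducible across platforms. |
| `edge_prob`, `weight_range` | — | generator parameters of `random_graph()`; weights are drawn uniformly from `weight_range` (unitless costs). |

## Listing conventions and the statistics

In undirected mode the path from node 1 to node 9 and its reversal are the
same path. The cluster task nevertheless lists both directions — an
unordered pair with $k$ unique paths contributes $2k$ direction-annotated
rows, matching the two-way results display the task emulates — while the
statistics count unique paths once (`group_by_length()` collapses a
forward/reverse pair). The tree and connect tasks have a distinguished
source, so they list forward paths only. Zero-hop self paths are never
listed.

`expected_paths()` counts the path relations a fully connected network
would realize: $n-1$ for a single-source tree, one per unordered pair
$\binom{n}{2}$ for an undirected cluster, one per ordered pair $n(n-1)$
for a directed cluster. The formula is our completion of the informal
notion "paths the network is supposed to develop if fully connected"; the
realized unique-path count is read against this denominator.

The Connected flag follows the task: global connectivity (strong
connectivity for directed graphs) for cluster-style runs, and
source-reachability for single-source runs — in a directed network the
same graph can be Connected from one node and not from another, as the
bundled directed example shows.

In weighted mode the reported *size* of a path is its total weight (the
optimized quantity); the hop count is still carried on every path.

## Worked example

```{r}
g <- toy_cluster_network()
res <- sp_cluster(g, c("1", "9"))
vapply(res$paths$paths, function(p) paste(p$nodes, collapse = "-"), "")
compute_stats(res$paths, g)
group_by_length(res$paths)
```

Nodes 1 and 9 are joined by exactly two four-hop paths, listed in both
directions; the statistics count them once each. The subnetwork is their
union:

```{r}
res$subnetwork
```

A useful invariant (tested on all fixtures and seeded instances): because
the union of all shortest paths keeps every edge of every optimal route,
re-running a task on its own extracted subnetwork reproduces the path set
exactly.

## Design choices where the design was open

* **Predecessor derivation.** Rather than maintaining predecessor sets
  during relaxation ("strictly better replaces, equal adds"), the package
  derives them in a single pass over the converged distances. The result
  is provably identical, it makes the Dijkstra and Bellman–Ford branches
  agree structurally by construction, and it avoids stale-predecessor
  bookkeeping in Bellman–Ford.
* **Nearest-member semantics of `connect_isolated()`.** With $d^\* =
  \min_m d(s, m)$ over the member set, the result keeps, for every member
  at distance $d^\*$, its shortest paths whose interior contains no member
  of the set. A member reachable only through other members develops no
  direct shortest-path relation with the source and is excluded — with
  positive weights the interior-member rule is implied by minimality of
  $d^\*$, but it is enforced explicitly so zero-weight corner cases cannot
  smuggle members into path interiors.
* **Duplicate edges** collapse to one edge per `(source, target, label)`
  triple, and duplicate weight entries collapse to the minimum with a
  warning: shortest-path semantics only ever use the cheapest parallel
  edge.
* **Weight-table headers.** A first row whose fields are all non-numeric
  is treated as a header; a row with numeric-looking endpoints and a
  malformed weight is a parse error, not a header.
* **Portable seeding.** `random_graph()` uses a Park–Miller minimal
  standard LCG implemented in the package (exact in double arithmetic)
  instead of R's session RNG, so a seed denotes the same graph on every
  platform and R version. Because the raw LCG state is linear in the seed,
  nearby seeds are decorrelated by a fixed 16-step warm-up after seeding.

## What the synthetic generator does and does not emulate

`random_graph()` draws Erdős–Rényi $G(n, p)$ graphs with optional uniform
weights. That is the right substrate for correctness testing — the
oracle-based suite compares the enumeration against exhaustive brute force
over all simple paths and distances against an independent Floyd–Warshall
implementation on hundreds of seeded instances (directed/undirected ×
unweighted/weighted, $n \le 10$, $p = 0.35$; sizes chosen so exhaustive
enumeration stays tractable) — but it does *not* reproduce the degree
heterogeneity, hubs, or clustering of real interactomes. Passing tests
certify algorithmic correctness on arbitrary topologies of this scale, not
biological realism or performance on hub-dominated million-edge networks.

## Known limitations

* The core is single-threaded and exact; no k-shortest-paths, A\*, or
  landmark approximations are provided.
* All-pairs statistics instantiate every per-pair path list; on large
  dense networks with massive tie structure, memory grows with the number
  of tied paths (mitigated by `max_paths`).
* Negative weights are supported only in directed graphs in practice (see
  above), and graphs containing zero-weight ties on shortest routes are
  rejected rather than summarized.
* The bundled example networks are synthetic reconstructions that satisfy
  the documented behavioural claims (node/edge counts, path sequences,
  reachability); they are illustrations, not curated biological data.
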