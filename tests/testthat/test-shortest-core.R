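test_that("predecessor DAG on a line graph matches hand-computed values", {
  g <- spn_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
  dag <- shortest_dag(g, "A")
  expect_equal(dag$dist, c(A = 0, B = 1, C = 2))
  expect_equal(dag$preds, list(A = character(), B = "A", C = "B"))
  expect_error(shortest_dag(g, "Q"), "Q", class = "spn_unknown_node")
})

test_that("unreachable targets are absent from dist and enumerate to empty", {
  gd <- toy_directed_network()
  dag <- shortest_dag(gd, "2")
  expect_false("1" %in% names(dag$dist))
  expect_length(enumerate_paths(dag, "1"), 0L)
  # target equal to source yields the single zero-hop path
  self <- enumerate_paths(dag, "2")
  expect_length(self, 1L)
  expect_identical(self[[1]]$nodes, "2")
  expect_equal(self[[1]]$hops, 0L)
})

test_that("enumerated path sets match brute force and Floyd-Warshall on seeded graphs", {
  grid <- oracle_grid(8)  # 32 graphs here; the full sweep runs in the acceptance suite
  for (r in seq_len(nrow(grid))) {
    g <- random_graph(grid$n[r], 0.35, directed = grid$directed[r],
                      weighted = grid$weighted[r], weight_range = c(0.5, 2),
                      seed = grid$seed[r] + 100L * r)
    D <- fw_dist(g)
    for (s in g$nodes) {
      dag <- shortest_dag(g, s)
      for (t in g$nodes) {
        expected <- brute_force_paths(g, s, t)
        got <- lapply(enumerate_paths(dag, t), `[[`, "nodes")
        expect_identical(got, expected)
        if (is.finite(D[s, t])) {
          expect_equal(unname(dag$dist[t]), D[s, t], tolerance = 1e-9)
        } else {
          expect_false(t %in% names(dag$dist))
        }
      }
    }
  }
})

test_that("every enumerated path's summed edge weights equal the target distance", {
  for (seed in 1:10) {
    g <- random_graph(8, 0.4, weighted = TRUE, weight_range = c(0.2, 3),
                      seed = seed)
    wlut <- structure(g$edges$weight,
                      names = paste(g$edges$from, g$edges$to, sep = "\t"))
    wlut <- c(wlut, structure(g$edges$weight,
                              names = paste(g$edges$to, g$edges$from, sep = "\t")))
    for (s in g$nodes) {
      dag <- shortest_dag(g, s)
      for (t in names(dag$dist)) {
        for (p in enumerate_paths(dag, t)) {
          if (p$hops == 0L) next
          sum_w <- sum(wlut[paste(p$nodes[-length(p$nodes)], p$nodes[-1],
                                  sep = "\t")])
          expect_equal(sum_w, unname(dag$dist[t]), tolerance = 1e-9)
          expect_equal(p$weight, unname(dag$dist[t]))
          expect_true(anyDuplicated(p$nodes) == 0L)  # simple path
        }
      }
    }
  }
})

test_that("unit-weight graphs reproduce the unweighted results", {
  for (seed in 1:6) {
    g <- random_graph(8, 0.35, directed = seed %% 2L == 0L, seed = seed)
    gu <- spn_graph(edges = g$edges, nodes = g$nodes, directed = g$directed,
                    weights = rep(1, nrow(g$edges)))
    for (s in g$nodes) {
      d1 <- shortest_dag(g, s)
      d2 <- shortest_dag(gu, s)
      expect_equal(d2$dist, d1$dist)
      expect_identical(d2$preds, d1$preds)
    }
  }
})

test_that("Dijkstra and Bellman-Ford branches produce identical predecessor DAGs", {
  for (seed in 1:10) {
    g <- random_graph(8, 0.4, directed = seed %% 2L == 0L, weighted = TRUE,
                      weight_range = c(0.1, 2.5), seed = seed)
    for (s in g$nodes) {
      expect_identical(shortest_dag(g, s, method = "dijkstra"),
                       shortest_dag(g, s, method = "bellman_ford"))
    }
  }
  gneg <- spn_graph(data.frame(from = "A", to = "B"), directed = TRUE,
                    weights = -1)
  expect_error(shortest_dag(gneg, "A", method = "dijkstra"),
               class = "spn_argument")
})

test_that("negative weights are handled soundly", {
  # negative edges without a negative cycle: distances match Floyd-Warshall
  g <- spn_graph(data.frame(from = c("A", "A", "B", "C"),
                            to   = c("B", "C", "D", "D")),
                 directed = TRUE, weights = c(2, 5, -4, -1))
  dag <- shortest_dag(g, "A")
  expect_equal(unname(dag$dist[c("B", "C", "D")]), c(2, 5, -2))
  expect_equal(dag$preds$D, "B")

  # a reachable negative-total-weight cycle is an error naming one cycle
  gc <- spn_graph(data.frame(from = c("A", "B", "C", "C"),
                             to   = c("B", "C", "A", "D")),
                  directed = TRUE, weights = c(1, -3, 1, 1))
  expect_error(shortest_dag(gc, "A"), "cycle", class = "spn_negative_cycle")

  # an unreachable negative cycle does not poison other sources
  gu <- spn_graph(data.frame(from = c("S", "A", "B"),
                             to   = c("T", "B", "A")),
                  directed = TRUE, weights = c(1, -1, -1))
  expect_equal(unname(shortest_dag(gu, "S")$dist["T"]), 1)

  # an undirected negative edge is itself a two-edge negative cycle
  gn <- spn_graph(data.frame(from = "A", to = "B"), weights = -1)
  expect_error(shortest_dag(gn, "A"), class = "spn_negative_cycle")
})

test_that("zero-total-weight cycles on shortest paths raise the degenerate-cycle error", {
  # zero cycle through the source
  g0 <- spn_graph(data.frame(from = c("A", "B"), to = c("B", "A")),
                  directed = TRUE, weights = c(0, 0))
  expect_error(shortest_dag(g0, "A"), class = "spn_degenerate_cycle")

  # zero cycle between two equidistant interior nodes
  g1 <- spn_graph(data.frame(from = c("S", "S", "B", "C"),
                             to   = c("B", "C", "C", "B")),
                  directed = TRUE, weights = c(1, 1, 0, 0))
  expect_error(shortest_dag(g1, "S"), class = "spn_degenerate_cycle")

  # an undirected zero-weight edge on a shortest path is degenerate too
  g2 <- spn_graph(data.frame(from = "A", to = "B"), weights = 0)
  expect_error(shortest_dag(g2, "A"), class = "spn_degenerate_cycle")

  # but a zero-weight edge off every shortest path is harmless
  g3 <- spn_graph(data.frame(from = c("S", "B"), to = c("A", "C")),
                  directed = TRUE, weights = c(1, 0))
  expect_equal(unname(shortest_dag(g3, "S")$dist), c(1, 0))
})

test_that("enumeration order is lexicographic, deterministic, and capped", {
  # chain of k diamonds: 2^k equal shortest paths
  k <- 5L
  from <- character(); to <- character()
  for (i in seq_len(k)) {
    m0 <- paste0("m", i - 1L); m1 <- paste0("m", i)
    a <- paste0("a", i); b <- paste0("b", i)
    from <- c(from, m0, m0, a, b)
    to <- c(to, a, b, m1, m1)
  }
  g <- spn_graph(data.frame(from = from, to = to), directed = TRUE)
  dag <- shortest_dag(g, "m0")
  all32 <- enumerate_paths(dag, paste0("m", k))
  expect_length(all32, 32L)
  expect_false(attr(all32, "truncated"))
  keys <- vapply(all32, function(p) paste(p$nodes, collapse = "|"), character(1))
  expect_identical(keys, sort(keys, method = "radix"))

  capped <- enumerate_paths(dag, paste0("m", k), max_paths = 10)
  expect_length(capped, 10L)
  expect_true(attr(capped, "truncated"))
  expect_identical(lapply(capped, `[[`, "nodes"),
                   lapply(all32[1:10], `[[`, "nodes"))

  # two runs are identical objects
  expect_identical(enumerate_paths(shortest_dag(g, "m0"), "m5"), all32)
})

test_that("all_pairs covers ordered pairs and is symmetric on undirected graphs", {
  g1 <- spn_graph(nodes = "only")
  ap1 <- all_pairs(g1)
  expect_length(ap1, 1L)
  expect_identical(ap1[["only\tonly"]][[1]]$nodes, "only")

  for (seed in 1:5) {
    g <- random_graph(7, 0.35, seed = seed)
    ap <- all_pairs(g)
    for (s in g$nodes) for (t in g$nodes) {
      fwd <- lapply(ap[[paste(s, t, sep = "\t")]], `[[`, "nodes")
      bwd <- lapply(ap[[paste(t, s, sep = "\t")]], function(n) rev(n$nodes))
      bwd <- bwd[order(vapply(bwd, paste, character(1), collapse = "\t"),
                       method = "radix")]
      expect_identical(fwd, bwd)
    }
  }
})
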