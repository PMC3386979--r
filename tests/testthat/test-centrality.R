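test_that("betweenness matches hand-computed small networks", {
  # star: every leaf pair's unique geodesic passes the hub
  st <- star_graph(3)
  b <- betweenness(st)
  expect_equal(unname(b["hub"]), 1.0)
  expect_equal(unname(b[-1]), rep(0, 3))

  # path a-b-c: single interior node mediates the only pair
  p3 <- path_graph(3)
  expect_equal(unname(betweenness(p3)), c(0, 1, 0))

  # 5-cycle: each node is interior of exactly one distance-2 pair
  expect_equal(unname(betweenness(cycle_graph(5))), rep(1 / 6, 5),
               tolerance = 1e-15)

  # two disjoint edges: no pair has an interior node
  two <- projected_network("drug", c("a", "b", "c", "d"),
                           from = c("a", "c"), to = c("b", "d"),
                           weight = c(1L, 1L))
  expect_equal(unname(betweenness(two)), rep(0, 4))

  # complete graph: every pair adjacent
  expect_equal(unname(betweenness(complete_graph(5))), rep(0, 5))

  expect_error(betweenness(projected_network("drug", character())),
               "empty network")
})

test_that("betweenness ignores edge weights when finding geodesics", {
  # heavy direct edge a-b must not push geodesics through c
  pn <- projected_network("drug", c("a", "b", "c"),
                          from = c("a", "a", "b"), to = c("b", "c", "c"),
                          weight = c(9L, 1L, 1L))
  expect_equal(unname(betweenness(pn)), rep(0, 3))
})

test_that("small networks return all-zero betweenness", {
  expect_equal(unname(betweenness(projected_network("drug", "x"))), 0)
  pn2 <- projected_network("drug", c("x", "y"), "x", "y", 1L)
  expect_equal(unname(betweenness(pn2)), c(0, 0))
})

test_that("brute-force oracle refuses oversized networks", {
  big <- projected_network("drug", sprintf("n%03d", 1:65))
  expect_error(betweenness_bruteforce(big), "oracle size limit")
})

test_that("efficient and brute-force betweenness agree on random graphs", {
  for (seed in 1:60) {
    n <- sample(3:12, 1)
    pn <- rand_projected(n, p = sample(c(0.2, 0.5, 0.8), 1), seed = seed)
    expect_lt(max(abs(betweenness(pn) - betweenness_bruteforce(pn))), 1e-12)
  }
})

test_that("betweenness agrees with an established implementation", {
  skip_if_not_installed("igraph")
  pairs <- rand_bipartite_pairs(30, 40, 0.08, seed = 99)
  pn <- project(build_bipartite(pairs), "drug")
  g <- igraph::graph_from_data_frame(pn$edges[, 1:2], directed = FALSE,
                                     vertices = pn$nodes)
  ref <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  expect_equal(unname(betweenness(pn)), unname(ref[pn$nodes]),
               tolerance = 1e-12)
})

test_that("closed forms hold for paths and stars", {
  for (n in 4:10) {
    b <- betweenness(path_graph(n))
    expected <- 2 * (seq_len(n) - 1) * (n - seq_len(n)) / ((n - 1) * (n - 2))
    expect_equal(unname(b), expected, tolerance = 1e-14)
  }
  for (leaves in 2:9) {
    b <- betweenness(star_graph(leaves))
    expect_equal(unname(b["hub"]), 1.0)
    # 1 is attained only by the star centre
    expect_true(all(b[-1] == 0))
  }
})

test_that("betweenness is in [0,1], zero for isolates, permutation-invariant", {
  for (seed in 1:20) {
    pn <- rand_projected(sample(3:12, 1), runif(1, 0.1, 0.9), seed = seed)
    b <- betweenness(pn)
    expect_true(all(b >= 0 & b <= 1))
    expect_true(all(b[degrees(pn) == 0L] == 0))

    # relabelling nodes permutes the output identically
    set.seed(seed + 1000)
    perm <- sample(seq_along(pn$nodes))
    pn2 <- projected_network(pn$mode, pn$nodes[perm], pn$edges$from,
                             pn$edges$to, pn$edges$weight)
    expect_equal(betweenness(pn2)[pn$nodes], b[pn$nodes])
  }
})

test_that("ranking sorts by betweenness then id, with consecutive ranks", {
  ct <- data.frame(node_id = c("a", "b", "c"),
                   betweenness = c(0.5, 0.9, 0.5),
                   stringsAsFactors = FALSE)
  rk <- rank_nodes(ct, k = 3)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$node_id, c("b", "a", "c")) # tie broken alphabetically
  expect_equal(rk$betweenness, c(0.9, 0.5, 0.5))

  expect_equal(nrow(rank_nodes(ct[1, ], k = 20)), 1L) # k truncated
  expect_error(rank_nodes(ct, k = 0), "positive")

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    tab <- data.frame(
      node_id = sample(sprintf("x%03d", 1:n)),
      betweenness = round(runif(n), 2), # rounding forces ties
      stringsAsFactors = FALSE)
    rk <- rank_nodes(tab, k = n)
    ref <- tab[order(-tab$betweenness, tab$node_id, method = "radix"), ]
    expect_equal(rk$node_id, ref$node_id)
    expect_equal(rk$rank, seq_len(n))
  }
})

test_that("centrality tables carry one row per node, isolates at zero", {
  pairs <- drug_target_pairs(c("A", "A", "B", "C"), c("t1", "t2", "t2", "t3"))
  pn <- project(build_bipartite(pairs), "drug")
  ct <- centrality_table(pn)
  expect_equal(ct$node_id, pn$nodes)
  expect_equal(attr(ct, "mode"), "drug")
  expect_equal(ct$betweenness[ct$node_id == "C"], 0)
  expect_equal(ct$degree[ct$node_id == "C"], 0L)
})
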