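test_that("pair records are validated and normalized", {
  p <- drug_target_pairs(c(" A ", "B"), c("t1", "t2"))
  expect_equal(p$drug_id, c("A", "B")) # surrounding whitespace trimmed
  expect_equal(p$multiplicity, c(1L, 1L))
  expect_error(drug_target_pairs("", "t1"), "empty")
  expect_error(drug_target_pairs("a\tb", "t1"), "tab")
  expect_error(drug_target_pairs("A", "t1", multiplicity = 0), "positive")
  expect_error(drug_target_pairs("A", "t1", multiplicity = 1.5), "positive")
})

test_that("bipartite construction merges duplicates and rejects bad input", {
  p <- drug_target_pairs(c("A", "A", "B"), c("t1", "t2", "t2"))
  net <- build_bipartite(p)
  expect_equal(net$drugs, c("A", "B"))
  expect_equal(net$targets, c("t1", "t2"))
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1L))

  # duplicate records merge by summing multiplicity; edge count drops
  dup <- drug_target_pairs(c("A", "A", "B"), c("t1", "t1", "t2"))
  net2 <- build_bipartite(dup)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(net2$edges$weight[net2$edges$drug == "A"], 2L)

  expect_error(build_bipartite(drug_target_pairs(character(), character())),
               "empty input")
  expect_error(
    build_bipartite(drug_target_pairs(c("A", "t1"), c("t1", "t2"))),
    "bipartite violation.*t1")
})

test_that("average targets per drug counts distinct edges only", {
  net <- build_bipartite(drug_target_pairs(c("A", "A", "B"),
                                           c("t1", "t2", "t3")))
  expect_equal(avg_targets_per_drug(net), 1.5)
  # multiplicity does not inflate the count
  net2 <- build_bipartite(drug_target_pairs(c("A", "A", "B"),
                                            c("t1", "t1", "t2"),
                                            multiplicity = c(1, 1, 1)))
  expect_equal(avg_targets_per_drug(net2), 1.0)
  net3 <- build_bipartite(drug_target_pairs("A", "t1"))
  expect_equal(avg_targets_per_drug(net3), 1.0)
})

test_that("projection weights count distinct shared partners", {
  net <- build_bipartite(drug_target_pairs(c("A", "A", "B", "B"),
                                           c("t1", "t2", "t1", "t2")))
  pd <- project(net, "drug")
  expect_equal(pd$edges,
               data.frame(from = "A", to = "B", weight = 2L,
                          stringsAsFactors = FALSE))
  pt <- project(net, "target")
  expect_equal(pt$edges$weight, 2L)

  # multiplicity on the two-mode edge is invisible to the projection
  netm <- build_bipartite(drug_target_pairs(
    c("A", "A", "A", "B"), c("t1", "t1", "t2", "t1"),
    multiplicity = c(5, 1, 1, 1)))
  expect_equal(project(netm, "drug")$edges$weight, 1L)
})

test_that("drugs sharing no target stay in the node list as isolates", {
  net <- build_bipartite(drug_target_pairs(c("A", "A", "B", "C"),
                                           c("t1", "t2", "t2", "t3")))
  pd <- project(net, "drug")
  expect_setequal(pd$nodes, c("A", "B", "C"))
  deg <- degrees(pd)
  expect_equal(unname(deg["C"]), 0L)
  expect_false("C" %in% c(pd$edges$from, pd$edges$to))
})

test_that("degree is the distinct-neighbour count, blind to weights", {
  tri <- projected_network("drug", c("a", "b", "c"),
                           from = c("a", "a", "b"), to = c("b", "c", "c"),
                           weight = c(3L, 1L, 1L))
  expect_equal(unname(degrees(tri)), c(2L, 2L, 2L))
  iso <- projected_network("drug", "lonely")
  expect_equal(unname(degrees(iso)), 0L)
  for (seed in 1:20) {
    pn <- rand_projected(n = sample(2:12, 1), p = runif(1, 0.1, 0.9),
                         seed = seed)
    nb <- lapply(pn$nodes, function(v) {
      unique(c(pn$edges$to[pn$edges$from == v],
               pn$edges$from[pn$edges$to == v]))
    })
    expect_equal(unname(degrees(pn)), lengths(nb))
  }
})

test_that("projection invariants hold on random bipartite networks", {
  for (seed in 1:30) {
    pairs <- rand_bipartite_pairs(sample(2:12, 1), sample(2:12, 1),
                                  runif(1, 0.1, 0.6), seed = seed)
    net <- build_bipartite(pairs)
    pd <- project(net, "drug")

    # node conservation: all drugs kept, isolates included
    expect_equal(pd$nodes, net$drugs)

    # weight bound: shared partners cannot exceed either drug's target count
    if (nrow(pd$edges) > 0L) {
      tcount <- table(net$edges$drug)
      expect_true(all(pd$edges$weight <=
                        pmin(as.integer(tcount[pd$edges$from]),
                             as.integer(tcount[pd$edges$to]))))
    }

    # handshake: degree sum is even
    expect_identical(sum(degrees(pd)) %% 2L, 0L)

    # role-swap symmetry: swapping drug/target roles swaps the projections
    swapped <- build_bipartite(drug_target_pairs(pairs$target_id,
                                                 pairs$drug_id))
    ps <- project(swapped, "drug")
    pt <- project(net, "target")
    expect_equal(edges_sorted(ps), edges_sorted(pt))
    expect_setequal(ps$nodes, pt$nodes)
  }
})
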