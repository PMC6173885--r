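test_that("two-level neighborhood is the radius-2 undirected BFS ball", {
  # path graph A->B->C->D, seeded at A, stops after two hops
  path <- regnet(data.frame(regulator = c("A", "B", "C"),
                            target = c("B", "C", "D")),
                 c(A = TRUE, B = TRUE, C = TRUE, D = FALSE))
  sub <- two_level_neighborhood(path, "A")
  expect_setequal(sub$nodes, c("A", "B", "C"))

  # isolated seed
  iso <- regnet(data.frame(regulator = "A", target = "B"),
                c(A = TRUE, B = FALSE, Z = FALSE))
  sub <- two_level_neighborhood(iso, "Z")
  expect_equal(sub$nodes, "Z")
  expect_equal(n_edges(sub), 0)

  expect_error(two_level_neighborhood(path, "nope"), "nope")

  # random digraphs against the BFS oracle, every node at undirected
  # distance <= 2 and none beyond
  for (s in 1:5) {
    net <- random_regnet(8, 22, 45, seed = s)
    seed_node <- net$nodes[1 + (s %% n_nodes(net))]
    sub <- two_level_neighborhood(net, seed_node)
    expect_equal(sort(sub$nodes),
                 oracle_bfs_ball(net$edges, net$nodes, seed_node, 2))
  }
})

test_that("directed neighborhood expansion follows edge direction", {
  path <- regnet(data.frame(regulator = c("A", "B", "C"),
                            target = c("B", "C", "D")),
                 c(A = TRUE, B = TRUE, C = TRUE, D = FALSE))
  sub <- two_level_neighborhood(path, "B", directed = TRUE)
  expect_setequal(sub$nodes, c("B", "C", "D"))  # A is upstream, not reached
})

test_that("pruning applies the two steps once, in order", {
  # star: TF hub with 3 degree-1 leaves; leaves go at step 1
  star <- regnet(data.frame(regulator = "H", target = c("l1", "l2", "l3")),
                 c(H = TRUE, l1 = FALSE, l2 = FALSE, l3 = FALSE))
  sub <- two_level_neighborhood(star, "H")
  pruned <- prune_subnetwork(sub)
  expect_equal(pruned$nodes, "H")

  # a degree-1 seed is removed at step 1: the seed exemption belongs to the
  # TF step only
  pair <- regnet(data.frame(regulator = "A", target = "S"),
                 c(A = TRUE, S = FALSE))
  pruned <- prune_subnetwork(two_level_neighborhood(pair, "S"))
  expect_length(pruned$nodes, 0)
  prov <- attr(pruned, "provenance")
  expect_equal(prov[[2]]$step, "degree_prune")
  expect_equal(prov[[2]]$n_nodes, 0)

  # hand-enumerated fixture: C, D, E drop at step 1 (degree < 2); the
  # non-TF seed S survives step 2 by exemption
  edges <- data.frame(regulator = c("A", "B", "A", "C", "D"),
                      target = c("S", "S", "B", "A", "E"))
  net <- regnet(edges, c(S = FALSE, A = TRUE, B = TRUE, C = TRUE,
                         D = TRUE, E = FALSE))
  pruned <- prune_subnetwork(two_level_neighborhood(net, "S"))
  expect_setequal(pruned$nodes, c("S", "A", "B"))
  expect_equal(n_edges(pruned), 3)
})

test_that("pruning agrees with a literal re-statement on random networks", {
  for (s in 1:6) {
    net <- random_regnet(7, 8, 30, seed = 100 + s)
    seed_node <- net$nodes[1 + (s %% n_nodes(net))]
    sub <- two_level_neighborhood(net, seed_node)
    pruned <- prune_subnetwork(sub)
    oracle <- oracle_prune(sub$edges, sub$nodes, sub$is_tf, seed_node)
    expect_equal(sort(pruned$nodes), oracle$nodes)
    expect_setequal(paste(pruned$edges$regulator, pruned$edges$target),
                    paste(oracle$edges$regulator, oracle$edges$target))
  }
})

test_that("pruned subnetworks contain no non-seed non-TF and reprune monotonically", {
  # the recipe is a single ordered pass, so a second application may remove
  # TFs whose degree dropped when non-TFs were erased -- but it can never
  # add nodes, and the TF constraint is stable
  for (s in 1:6) {
    net <- random_regnet(6, 10, 35, seed = 200 + s)
    seed_node <- net$nodes[1 + (s %% n_nodes(net))]
    pruned <- build_seed_subnetwork(net, seed_node)
    non_seed <- setdiff(pruned$nodes, seed_node)
    expect_true(all(pruned$is_tf[non_seed]))
    again <- prune_subnetwork(pruned)
    expect_true(all(again$nodes %in% pruned$nodes))
    expect_true(all(again$is_tf[setdiff(again$nodes, seed_node)]))
  }
})

test_that("shared TFs intersect subnetworks, excluding the seeds", {
  # hub regulating everything: every pair of targets shares it
  hub <- regnet(data.frame(regulator = "H", target = sprintf("t%d", 1:5)),
                stats::setNames(c(TRUE, rep(FALSE, 5)),
                                c("H", sprintf("t%d", 1:5))))
  subs <- lapply(c("t1", "t2", "t3", "t4"),
                 function(x) build_seed_subnetwork(hub, x))
  res <- shared_tfs(subs)
  expect_equal(res$shared_tfs, "H")
  expect_equal(res$k, 1)

  # identical subnetworks: intersection is idempotent
  res2 <- shared_tfs(list(subs[[1]], subs[[1]]))
  expect_equal(res2$shared_tfs, "H")

  # disjoint subnetworks share nothing
  two <- regnet(data.frame(regulator = c("T1", "T2"), target = c("a", "b")),
                c(T1 = TRUE, T2 = TRUE, a = FALSE, b = FALSE))
  expect_equal(shared_tfs(lapply(c("a", "b"),
                                 function(x) build_seed_subnetwork(two, x)))$k, 0)

  expect_error(shared_tfs(subs[1]), "at least 2")

  # a TF seed does not count itself as a shared regulator
  net <- regnet(data.frame(regulator = c("P", "P", "M", "M", "M"),
                           target = c("a", "b", "a", "b", "P")),
                c(P = TRUE, M = TRUE, a = FALSE, b = FALSE))
  subs <- lapply(c("P", "a", "b"), function(x) build_seed_subnetwork(net, x))
  res <- shared_tfs(subs)
  expect_false("P" %in% res$shared_tfs)
  res_incl <- shared_tfs(subs, exclude_seeds = FALSE)
  expect_true("P" %in% res_incl$shared_tfs)
})

test_that("shared-TF intersection is order-invariant and anti-monotone", {
  net <- random_regnet(8, 12, 50, seed = 42)
  seeds <- net$nodes[c(2, 5, 9, 14)]
  subs <- lapply(seeds, function(x) build_seed_subnetwork(net, x))
  base <- shared_tfs(subs)
  perm <- shared_tfs(subs[c(3, 1, 4, 2)])
  expect_equal(perm$shared_tfs, base$shared_tfs)
  # adding one more subnetwork can only shrink the intersection
  extra <- build_seed_subnetwork(net, net$nodes[17])
  grown <- shared_tfs(c(subs, list(extra)))
  expect_true(all(grown$shared_tfs %in% base$shared_tfs))
  expect_lte(grown$k, base$k)
})
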