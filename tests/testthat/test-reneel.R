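# The RenEEL ensemble scheme: base heuristic, core groups, graph reduction,
# the reduce/replace loop, and the exhaustive oracle.

test_that("the base heuristic finds the two-triangle optimum", {
  g <- worked_example_graph()
  for (s in c(1, 7, 33)) {
    p <- base_heuristic(g, chi = 0, seed = s)
    expect_gte(generalized_modularity_density(g, p, 0), 0.357142)
  }
  # deterministic for a fixed seed
  expect_identical(base_heuristic(g, 0, 5), base_heuristic(g, 0, 5))
})

test_that("single-edge graph resolves to whichever option scores higher", {
  g <- ugraph(data.frame(u = 1, v = 2, weight = 3))
  for (chi in c(0, 1)) {
    p <- base_heuristic(g, chi, seed = 2)
    best <- max(generalized_modularity_density(g, partition(1:2, c(1, 1)), chi),
                generalized_modularity_density(g, partition(1:2, 1:2), chi))
    expect_equal(generalized_modularity_density(g, p, chi), best)
  }
})

test_that("core groups intersect the ensemble's co-membership relations", {
  p <- partition(1:4, c(1, 1, 2, 2))
  same <- core_groups(list(p, p, p))
  expect_equal(partition_communities(same),
               partition_communities(p), ignore_attr = TRUE)
  q <- partition(1:4, c(1, 2, 1, 2))   # {13|24}
  cg <- core_groups(list(p, q))
  expect_equal(length(partition_communities(cg)), 4)  # all singletons
  expect_equal(length(partition_communities(core_groups(list(q)))), 2)
  expect_error(core_groups(list()), "empty")
  expect_error(core_groups(list(p, partition(1:3, 1:3))), "different node sets")
})

test_that("graph reduction preserves weights, sizes, and scoring exactly", {
  g <- worked_example_graph()
  # singleton grouping: reduced graph isomorphic to g
  singl <- partition(letters[1:6], 1:6)
  r0 <- reduce_graph(g, singl)
  expect_equal(nrow(r0$nodes), 6)
  expect_equal(sum(r0$edges$weight), 7)
  expect_equal(r0$nodes$internal, rep(0, 6))

  # two-triangle grouping: 2 nodes, inter-weight 1, internal 3 and 3
  tri <- partition(letters[1:6], c(1, 1, 1, 2, 2, 2))
  r2 <- reduce_graph(g, tri)
  expect_equal(nrow(r2$nodes), 2)
  expect_equal(r2$edges$weight, 1)
  expect_equal(sort(r2$nodes$internal), c(3, 3))

  # one-community partition scores 0 on both representations
  expect_equal(generalized_modularity_density(
    r2, partition(r2$nodes$id, c(1, 1)), 0), 0)
  expect_equal(generalized_modularity_density(
    g, partition(letters[1:6], rep(1, 6)), 0), 0)
})

test_that("reduced-graph scoring equals expanded original-graph scoring", {
  for (s in 1:6) {
    g <- random_small_graph(s, n_range = 7:9)
    ids <- g$nodes$id
    set.seed(s)
    grouping <- partition(ids, sample(1:3, length(ids), replace = TRUE))
    rg <- reduce_graph(g, grouping)
    set.seed(s + 50)
    p_red <- partition(rg$nodes$id,
                       sample(1:2, nrow(rg$nodes), replace = TRUE))
    p_exp <- connhub:::expand_partition(rg, p_red)
    for (chi in c(0, 0.7)) {
      expect_equal(generalized_modularity_density(rg, p_red, chi),
                   generalized_modularity_density(g, p_exp, chi),
                   tolerance = 1e-12)
    }
  }
})

test_that("reneel reaches the oracle optimum on structured small graphs", {
  g <- worked_example_graph()
  res <- reneel_maximize(g, chi = 0, ensemble_size = 6, seed = 3)
  ex <- exhaustive_best_partition(g, chi = 0)
  expect_equal(res$score, ex$score, tolerance = 1e-12)
  expect_equal(length(partition_communities(res$partition)), 2)

  # two disconnected 4-cliques -> exactly the two cliques
  cl <- expand.grid(u = 1:4, v = 1:4)
  cl <- cl[cl$u < cl$v, ]
  g2 <- ugraph(data.frame(u = c(cl$u, cl$u + 4), v = c(cl$v, cl$v + 4),
                          weight = 1))
  res2 <- reneel_maximize(g2, chi = 0, ensemble_size = 6, seed = 1)
  comms <- partition_communities(res2$partition)
  expect_equal(lapply(comms, sort)[order(vapply(comms, min, character(1)))],
               list(as.character(1:4), as.character(5:8)),
               ignore_attr = TRUE)
})

test_that("reneel is deterministic, monotone, and terminates by consensus", {
  g <- random_small_graph(17, n_range = 8:8)
  a <- reneel_maximize(g, chi = 0.5, ensemble_size = 5, seed = 11)
  b <- reneel_maximize(g, chi = 0.5, ensemble_size = 5, seed = 11)
  expect_identical(a$partition, b$partition)
  expect_identical(a$score, b$score)
  expect_true(a$diagnostics$converged)
  # best-so-far trajectory never decreases, and the final score is at least
  # the score of every initial ensemble member
  expect_true(all(diff(a$diagnostics$best_score_trajectory) >= -1e-12))
  expect_gte(a$score, a$diagnostics$best_score_trajectory[1] - 1e-12)
  # capacity shrinks to one by the end
  expect_equal(utils::tail(a$diagnostics$capacity_trajectory, 1), 1)
  expect_error(reneel_maximize(g, ensemble_size = 1), "ensemble_size")
})

test_that("exhaustive enumeration handles the documented small cases", {
  g2 <- ugraph(data.frame(u = 1, v = 2, weight = 1))
  ex <- exhaustive_best_partition(g2, 0)
  expect_equal(ex$score, 0)
  expect_equal(length(partition_communities(ex$partition)), 1)

  tri <- ugraph(data.frame(u = c(1, 2, 1), v = c(2, 3, 3), weight = 1))
  ext <- exhaustive_best_partition(tri, 0)
  expect_equal(length(partition_communities(ext$partition)), 1)

  big <- ugraph(data.frame(u = 1:11, v = c(2:11, 1), weight = 1))
  expect_error(exhaustive_best_partition(big, 0), "10 nodes")
})
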