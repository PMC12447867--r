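# Rankings, partner counts, primacy, reciprocity, and circuit ratios.

test_that("ranking sums input and output weights with stable tie-breaks", {
  # star: hub 9 with 5 in-edges (w=2) and 3 out-edges (w=4)
  x <- connectome(neuron_df(1:9, instance = c(rep(NA, 8), "hub_R")),
                  edge_df(c(1:5, 9, 9, 9), c(rep(9, 5), 6, 7, 8),
                          c(rep(2, 5), rep(4, 3))))
  r <- rank_by_total_synapses(x, 3)
  expect_equal(r$bodyId[1], 9)
  expect_equal(r$input_weight[1], 10)
  expect_equal(r$output_weight[1], 12)
  expect_equal(r$total_weight[1], 22)
  expect_equal(r$label[1], "hub_R")

  empty <- connectome(neuron_df(integer(0)),
                      edge_df(integer(0), integer(0), integer(0)))
  expect_equal(nrow(rank_by_total_synapses(empty, 5)), 0)

  # equal totals -> ascending bodyId
  y <- connectome(neuron_df(1:3), edge_df(c(3, 3), c(1, 2), c(4, 4)))
  ry <- rank_by_total_synapses(y, 3)
  expect_equal(ry$bodyId, c(3, 1, 2))
  expect_error(rank_by_total_synapses(y, 0), "top_n")
})

test_that("unique partner counts classify pre/post/both at the threshold", {
  x <- partner_fixture()
  pc <- count_unique_partners(x, 1, threshold = 3)
  expect_equal(pc, list(pre_only = 1, post_only = 1, both = 1, total = 3))
  pc1 <- count_unique_partners(x, 1, threshold = 1)
  expect_equal(pc1$total, 4)   # weak partner D now counted
  iso <- count_unique_partners(x, 5, threshold = 3)
  expect_equal(iso$total, 0)
  expect_error(count_unique_partners(x, 42), "unknown")
})

test_that("partner totals are non-increasing in the threshold", {
  for (s in 1:4) {
    x <- random_connectome(s)
    for (id in x$neurons$bodyId[1:4]) {
      tots <- vapply(1:6, function(t) {
        count_unique_partners(x, id, t)$total
      }, numeric(1))
      expect_true(all(diff(tots) <= 0))
    }
  }
})

test_that("partner cell-type counts deduplicate and exclude untyped", {
  # partners of 1: ids 2,3 type X (pre), 4 type Y (pre+post), 5 untyped (pre)
  x <- connectome(
    neuron_df(1:5, type = c("Z", "X", "X", "Y", NA)),
    edge_df(c(2, 3, 4, 1, 5), c(1, 1, 1, 4, 1), c(5, 5, 5, 5, 5)))
  ct <- count_partner_celltypes(x, 1)
  expect_equal(ct, list(pre_only = 1, post_only = 0, both = 1, total = 2))
  ct2 <- count_partner_celltypes(x, 1, include_untyped = TRUE)
  expect_equal(ct2$total, 3)
})

test_that("median partner cell-type count matches per-neuron enumeration", {
  x <- random_connectome(11)
  per_neuron <- vapply(x$neurons$bodyId, function(id) {
    count_partner_celltypes(x, id, threshold = 3)$total
  }, numeric(1))
  expect_equal(median_partner_celltype_count(x, threshold = 3),
               stats::median(per_neuron))
  expect_gte(median_partner_celltype_count(x), min(per_neuron))
  expect_lte(median_partner_celltype_count(x), max(per_neuron))
  empty <- connectome(neuron_df(integer(0)),
                      edge_df(integer(0), integer(0), integer(0)))
  expect_error(median_partner_celltype_count(empty), "empty")
})

test_that("primacy ranks the target among aggregated outputs", {
  mk <- function(weights) {
    # two source neurons of type S; outputs to target type T and types X, Y
    connectome(
      neuron_df(1:5, type = c("S", "S", "T", "X", "Y")),
      edge_df(c(1, 2, 1, 2, 1), c(3, 3, 4, 4, 5),
              c(weights[1] - 1, 1, weights[2] - 1, 1, weights[3])))
  }
  r <- compute_primacy(mk(c(150, 90, 20)), "S", "T")
  expect_equal(r$target_rank, 1)
  expect_true(r$is_primary)
  expect_true(r$is_strong)
  expect_equal(r$weight_to_target, 150)

  r2 <- compute_primacy(mk(c(150, 200, 20)), "S", "T")
  expect_equal(r2$target_rank, 2)
  expect_false(r2$is_primary)
  expect_true(r2$is_strong)

  r3 <- compute_primacy(mk(c(50, 50, 20)), "S", "T")
  expect_equal(r3$target_rank, 1)   # tie does not demote
  expect_true(r3$is_primary)
  expect_false(r3$is_strong)

  expect_error(compute_primacy(mk(c(10, 10, 10)), "nope", "T"), "unknown")
})

test_that("untyped postsynaptic weight can outrank the target when pooled", {
  x <- connectome(neuron_df(1:4, type = c("S", "T", NA, NA)),
                  edge_df(c(1, 1, 1), c(2, 3, 4), c(50, 40, 30)))
  pooled <- compute_primacy(x, "S", "T")
  expect_equal(pooled$target_rank, 2)   # untyped pool carries 70
  ignored <- compute_primacy(x, "S", "T", include_untyped = FALSE)
  expect_equal(ignored$target_rank, 1)
})

test_that("zero weight to the target ranks below every positive type", {
  x <- connectome(neuron_df(1:4, type = c("S", "T", "X", "Y")),
                  edge_df(c(1, 1), c(3, 4), c(10, 5)))
  r <- compute_primacy(x, "S", "T")
  expect_equal(r$weight_to_target, 0)
  expect_equal(r$target_rank, 3)
})

test_that("reciprocity requires both directions within a factor of two", {
  expect_true(classify_reciprocity(100, 60))
  expect_false(classify_reciprocity(100, 10))
  expect_false(classify_reciprocity(100, 0))
  expect_true(classify_reciprocity(50, 100))   # symmetric rule
  expect_true(classify_reciprocity(40, 80))    # boundary ratio 2 included
})

test_that("circuit input/output ratios are fractions of thresholded totals", {
  # inputs to 1: from circuit member 2 (w 5), outsider 3 (w 4)
  x <- connectome(neuron_df(1:3), edge_df(c(2, 3), c(1, 1), c(5, 4)))
  r <- circuit_io_ratio(x, circuit_ids = c(1, 2), n = 1)
  expect_equal(r$input_ratio, 5 / 9)
  expect_equal(r$output_ratio, 0)     # no outputs at all -> 0/0 rule
  all_in <- circuit_io_ratio(x, circuit_ids = 1:3, n = 1)
  expect_equal(all_in$input_ratio, 1)
})
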