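# Loading, validation, filtering, subconnectome extraction, symmetrization,
# and neuropil supercategory mapping.

write_tables <- function(neurons, edges) {
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  utils::write.csv(neurons, np, row.names = FALSE, na = "")
  utils::write.csv(edges, ep, row.names = FALSE, na = "")
  list(neurons = np, edges = ep)
}

test_that("loading round-trips a toy connectome and preserves records", {
  tf <- write_tables(neuron_df(1:3, type = c("X", "Y", NA)),
                     edge_df(c(1, 2), c(2, 3), c(4, 7), roi = c("SMP(R)", NA)))
  x <- load_connectome(tf$neurons, tf$edges)
  expect_s3_class(x, "connectome")
  expect_equal(nrow(x$neurons), 3)
  expect_equal(nrow(x$edges), 2)

  out <- write_tables(data.frame(), data.frame())  # reuse temp paths
  write_connectome(x, out$neurons, out$edges)
  y <- load_connectome(out$neurons, out$edges)
  expect_equal(y$edges[order(y$edges$bodyId_pre), ],
               x$edges[order(x$edges$bodyId_pre), ])
  expect_equal(y$neurons$bodyId, x$neurons$bodyId)
})

test_that("format violations are reported with position", {
  tf <- write_tables(neuron_df(1:2),
                     data.frame(bodyId_pre = 1, bodyId_post = 2,
                                weight = "2.5"))
  expect_error(load_connectome(tf$neurons, tf$edges), "row 1")

  tf2 <- write_tables(neuron_df(1:2)[, -1],
                      edge_df(1, 2, 3))
  expect_error(load_connectome(tf2$neurons, tf2$edges), "bodyId")
})

test_that("edges referencing unknown neurons obey strict/lenient modes", {
  neurons <- neuron_df(1:2)
  edges <- edge_df(c(1, 9), c(2, 1), c(3, 4))
  expect_error(connectome(neurons, edges, strict = TRUE), "absent")
  expect_message(x <- connectome(neurons, edges, strict = FALSE), "dropped 1")
  expect_equal(nrow(x$edges), 1)
  expect_equal(attr(x, "dropped_edges"), 1)
})

test_that("self-loops are removed at construction", {
  x <- connectome(neuron_df(1:2), edge_df(c(1, 1), c(1, 2), c(4, 3)))
  expect_equal(attr(x, "self_loops_removed"), 1)
  expect_equal(nrow(x$edges), 1)
})

test_that("weight filtering uses per-pair totals summed over roi rows", {
  x <- connectome(neuron_df(1:4),
                  edge_df(c(1, 1, 2, 3, 3), c(2, 3, 3, 4, 4),
                          c(5, 2, 3, 2, 2), roi = c(NA, NA, NA, "SMP(R)", "FB")))
  f <- filter_by_weight(x, 3)
  pt <- connhub:::pair_totals(f)
  expect_setequal(pt$total, c(5, 3, 4))        # pair 1->3 (total 2) dropped
  expect_equal(nrow(f$edges[f$edges$bodyId_pre == 3, ]), 2)  # roi split kept
  expect_identical(filter_by_weight(x, 1), x)  # threshold 1 is identity
})

test_that("weight filtering is idempotent and monotone", {
  for (s in 1:5) {
    x <- random_connectome(s)
    f3 <- filter_by_weight(x, 3)
    expect_equal(filter_by_weight(f3, 3)$edges, f3$edges)
    f5 <- filter_by_weight(x, 5)
    key <- function(c) paste(c$edges$bodyId_pre, c$edges$bodyId_post)
    expect_true(all(key(f5) %in% key(f3)))
  }
})

test_that("traced/uncropped restriction drops cropped neurons and their edges", {
  x <- connectome(neuron_df(1:3, cropped = c(FALSE, FALSE, TRUE)),
                  edge_df(c(1, 3, 2), c(2, 1, 3), c(4, 5, 6)))
  r <- restrict_traced_uncropped(x)
  expect_equal(r$neurons$bodyId, 1:2)
  expect_equal(nrow(r$edges), 1)           # only 1->2 survives
  all_ok <- connectome(neuron_df(1:3), edge_df(1, 2, 3))
  expect_equal(restrict_traced_uncropped(all_ok)$edges, all_ok$edges)
})

test_that("input subconnectome is the induced graph on presynaptic partners", {
  x <- subconn_fixture()
  s <- extract_input_subconnectome(x, 4)
  expect_setequal(s$neurons$bodyId, c(1, 2))   # A and B; weak B->T included
  expect_equal(nrow(s$edges), 1)
  expect_equal(s$edges$weight, 2)              # A->B(2) only
  expect_error(extract_input_subconnectome(x, 99), "unknown target")

  # target with no inputs -> empty
  y <- connectome(neuron_df(1:2), edge_df(1, 2, 3))
  expect_equal(nrow(extract_input_subconnectome(y, 1)$neurons), 0)

  # reciprocal partner included once; target never a member
  z <- connectome(neuron_df(1:2), edge_df(c(1, 2), c(2, 1), c(3, 4)))
  s2 <- extract_input_subconnectome(z, 1)
  expect_equal(s2$neurons$bodyId, 2)
})

test_that("symmetrization sums both directions and conserves weight", {
  x <- connectome(neuron_df(1:2), edge_df(c(1, 2), c(2, 1), c(2, 3)))
  g <- to_undirected(x)
  expect_equal(g$edges$weight, 5)
  one_way <- to_undirected(connectome(neuron_df(1:2), edge_df(1, 2, 2)))
  expect_equal(one_way$edges$weight, 2)
  for (s in 1:5) {
    rc <- random_connectome(s)
    g <- to_undirected(rc)
    expect_equal(sum(g$edges$weight), sum(rc$edges$weight))
    expect_setequal(g$nodes$id, rc$neurons$bodyId)
  }
})

test_that("roi supercategory mapping merges laterality and buckets unknowns", {
  m <- load_roi_map()
  expect_equal(map_roi_supercategory("SMP(R)", m), "SNP")
  expect_equal(map_roi_supercategory("SMP(L)", m), "SNP")
  expect_equal(map_roi_supercategory("SLP_L", m), "SNP")
  expect_equal(map_roi_supercategory("FB", m), "CX")
  expect_equal(map_roi_supercategory(NA, m), "NotPrimary")
  expect_equal(map_roi_supercategory("no-such-roi", m), "NotPrimary")
  expect_true(all(m$supercategory %in% c(connhub:::SUPERCATEGORIES,
                                         "NotPrimary")))
  # merging right/left variants never changes per-supercategory sums
  rois <- c("SMP(R)", "SMP(L)", "FB", "CRE(R)", NA)
  w <- c(5, 3, 2, 1, 4)
  merged <- tapply(w, map_roi_supercategory(rois, m), sum)
  expect_equal(unname(merged["SNP"]), 8)
  expect_equal(unname(merged["NotPrimary"]), 4)
})
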