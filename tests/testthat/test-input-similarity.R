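# Input vectors, cosine similarity, pooled module means, shuffle-null z.

test_that("input vectors exclude intra-subconnectome sources", {
  # sub = {1 (A), 2 (B)}; edges C(3)->A w4, A->B w2
  x <- connectome(neuron_df(1:3), edge_df(c(3, 1), c(1, 2), c(4, 2)))
  M <- build_input_vectors(x, c(1, 2))
  expect_equal(dim(M), c(2, 1))
  expect_equal(as.numeric(M["1", "3"]), 4)
  expect_equal(as.numeric(M["2", "3"]), 0)    # A->B removed with A's column
  expect_equal(attr(M, "zero_rows"), 1)
  expect_error(build_input_vectors(x, c(1, 99)), "absent")
  expect_warning(build_input_vectors(x, 1:3), "zero-width")
})

test_that("cosine similarity follows the inner-product formula", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_equal(z, 0)
  expect_error(cosine_similarity(1:3, 1:2), "length mismatch")
  # scale invariance
  set.seed(3)
  u <- runif(5); v <- runif(5)
  expect_equal(cosine_similarity(u * 17, v), cosine_similarity(u, v))
})

test_that("pooled module means capture within/between block structure", {
  # two modules of 2 rows; identical within, orthogonal across
  M <- sparse_mat(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                        c(0, 0, 2, 2), c(0, 0, 2, 2)),
                  as.character(1:4), as.character(101:104))
  p <- partition(1:4, c(1, 1, 2, 2))
  ps <- pooled_module_similarity(M, p)
  expect_equal(unclass(ps$means), matrix(c(1, 0, 0, 1), 2, 2),
               ignore_attr = TRUE)

  # all rows identical -> all means 1
  M2 <- sparse_mat(matrix(rep(c(1, 1, 0, 0), each = 4), 4, 4),
                   as.character(1:4), as.character(101:104))
  expect_equal(unclass(pooled_module_similarity(M2, p)$means),
               matrix(1, 2, 2), ignore_attr = TRUE)

  # singleton module: within-mean undefined
  p3 <- partition(1:4, c(1, 1, 2, 3))
  expect_true(is.na(pooled_module_similarity(M, p3)$means["3", "3"]))
})

test_that("shuffle z-scores are deterministic and flag degenerate nulls", {
  M <- sparse_mat(matrix(rep(c(1, 2, 0, 1), 4), 4, 4, byrow = TRUE),
                  as.character(1:4), as.character(11:14))
  p <- partition(1:4, c(1, 1, 2, 2))
  # identical rows: every shuffled mean equals the true mean, sd = 0
  expect_warning(ps <- shuffle_zscores(M, p, n_shuffles = 10, seed = 1),
                 "degenerate")
  expect_true(all(is.na(ps$z)))

  set.seed(9)
  M2 <- Matrix::Matrix(matrix(rpois(24, 3), 4, 6), sparse = TRUE)
  dimnames(M2) <- list(as.character(1:4), as.character(21:26))
  a <- shuffle_zscores(M2, p, n_shuffles = 25, seed = 7)
  b <- shuffle_zscores(M2, p, n_shuffles = 25, seed = 7)
  expect_identical(a$z, b$z)
  expect_error(shuffle_zscores(M2, p, n_shuffles = 1), "n_shuffles")
})

test_that("the pair-weighted grand mean is invariant under label shuffling", {
  set.seed(5)
  M <- Matrix::Matrix(matrix(rpois(60, 2), 10, 6), sparse = TRUE)
  dimnames(M) <- list(as.character(1:10), as.character(31:36))
  memb <- rep(1:2, each = 5)
  S <- connhub:::row_cosine_matrix(M)
  grand <- function(mm) {
    means <- connhub:::pool_means(S, mm)
    sizes <- table(mm)
    wts <- outer(as.numeric(sizes), as.numeric(sizes))
    diag(wts) <- choose(as.numeric(sizes), 2)
    wts[lower.tri(wts)] <- 0
    sum(means * wts, na.rm = TRUE) / sum(wts[!is.na(means)])
  }
  g0 <- grand(memb)
  for (s in 1:5) {
    set.seed(s)
    expect_equal(grand(sample(memb)), g0, tolerance = 1e-12)
  }
})
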