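# Shared fixture builders. All fixtures are constructed in code.

# minimal neuron table: every neuron traced and uncropped unless stated
neuron_df <- function(ids, type = NA_character_, instance = NA_character_,
                      traced = TRUE, cropped = FALSE) {
  n <- length(ids)
  data.frame(bodyId = ids, type = rep(type, length.out = n),
             instance = rep(instance, length.out = n),
             traced = rep(traced, length.out = n),
             cropped = rep(cropped, length.out = n))
}

# dense -> general sparse matrix with dimnames (avoids the automatic
# symmetric-class conversion, which shares a single dimnames vector)
sparse_mat <- function(m, rn, cn) {
  M <- methods::as(methods::as(Matrix::Matrix(m), "generalMatrix"),
                   "CsparseMatrix")
  dimnames(M) <- list(rn, cn)
  M
}

edge_df <- function(pre, post, weight, roi = NA_character_) {
  data.frame(bodyId_pre = pre, bodyId_post = post,
             roi = rep(roi, length.out = length(pre)), weight = weight)
}

# the 4-node fixture of the subconnectome example:
# A=1, B=2, C=3, T=4; edges A->T(5), B->T(1), A->B(2), C->A(4), T->B(9)
subconn_fixture <- function() {
  connectome(neuron_df(1:4),
             edge_df(c(1, 2, 1, 3, 4), c(4, 4, 2, 1, 2), c(5, 1, 2, 4, 9)))
}

# partner-count fixture: T=1, A=2, B=3, C=4, D=5
# A->T(5), T->A(3), B->T(4), T->C(7), D->T(2)
partner_fixture <- function() {
  connectome(neuron_df(1:5),
             edge_df(c(2, 1, 3, 1, 5), c(1, 2, 1, 4, 1), c(5, 3, 4, 7, 2)))
}

# seeded random weighted graph on n nodes (every node present, >= 1 edge)
random_small_graph <- function(seed, n_range = 4:8, p = 0.45, wmax = 5) {
  set.seed(seed)
  n <- if (length(n_range) == 1) n_range else sample(n_range, 1)
  repeat {
    ee <- expand.grid(u = 1:n, v = 1:n)
    ee <- ee[ee$u < ee$v, ]
    keep <- stats::runif(nrow(ee)) < p
    if (sum(keep) > 0) break
  }
  ugraph(data.frame(u = ee$u[keep], v = ee$v[keep],
                    weight = sample(seq_len(wmax), sum(keep), replace = TRUE)),
         nodes = data.frame(id = 1:n))
}

# seeded random connectome for property-style tests
random_connectome <- function(seed, n = 12, p = 0.3) {
  set.seed(seed)
  ee <- expand.grid(pre = 1:n, post = 1:n)
  ee <- ee[ee$pre != ee$post, ]
  keep <- stats::runif(nrow(ee)) < p
  ee <- ee[keep, , drop = FALSE]
  connectome(neuron_df(1:n, type = paste0("T", rep(1:4, length.out = n))),
             edge_df(ee$pre, ee$post, sample(1:9, nrow(ee), replace = TRUE)))
}
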