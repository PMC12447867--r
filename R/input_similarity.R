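# Brain-wide input vectors of subconnectome neurons, cosine similarity,
# within/between-module pooled means, and shuffle-null z-scores.
#
# Each subconnectome neuron n is described by the vector of synapse weights
# it receives from every neuron OUTSIDE the subconnectome; two neurons are
# similar when they draw input from the same external sources in the same
# proportions.

#' Build the external input-vector matrix of a subconnectome
#'
#' Rows are subconnectome neurons, columns all other neurons of the full
#' connectome; entry `(n, i)` is the synapse weight from column neuron `i`
#' onto row neuron `n`. Inputs arriving from other subconnectome members are
#' excluded (their columns do not exist), so similarity reflects shared
#' external drive only.
#'
#' @param full a [connectome()] (the full network).
#' @param sub_ids bodyIds of the subconnectome neurons, a proper subset of
#'   `full`'s neurons.
#' @return Sparse `Matrix::dgCMatrix` with dimnames; attribute `zero_rows`
#'   counts rows with no external input.
#' @export
build_input_vectors <- function(full, sub_ids) {
  stopifnot(inherits(full, "connectome"))
  sub_ids <- unique(sub_ids)
  if (!all(sub_ids %in% full$neurons$bodyId)) {
    stop("sub_ids contain bodyIds absent from the connectome", call. = FALSE)
  }
  ext_ids <- setdiff(full$neurons$bodyId, sub_ids)
  if (length(ext_ids) == 0) {
    warning("no neurons outside the subconnectome: zero-width matrix")
  }
  e <- full$edges
  sel <- e$bodyId_post %in% sub_ids & e$bodyId_pre %in% ext_ids
  e <- e[sel, , drop = FALSE]
  ri <- match(e$bodyId_post, sub_ids)
  ci <- match(e$bodyId_pre, ext_ids)
  M <- Matrix::sparseMatrix(
    i = ri, j = ci, x = e$weight,
    dims = c(length(sub_ids), length(ext_ids)),
    dimnames = list(as.character(sub_ids), as.character(ext_ids)))
  attr(M, "zero_rows") <- sum(Matrix::rowSums(M) == 0)
  M
}

#' Cosine similarity of two weight vectors
#'
#' `<u, v> / (||u|| ||v||)`; for non-negative weight vectors this lies in
#' `[0, 1]`: 0 for completely disjoint input sets, 1 for identical inputs in
#' identical proportion. A zero-norm vector yields similarity 0 (with a
#' warning), since it carries no input to compare.
#'
#' @param u,v numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm vector: similarity reported as 0")
    return(0)
  }
  sum(u * v) / (nu * nv)
}

# full pairwise cosine similarity matrix of the rows of M (zero rows -> 0)
row_cosine_matrix <- function(M) {
  nrm <- sqrt(Matrix::rowSums(M^2))
  inv <- ifelse(nrm > 0, 1 / nrm, 0)
  S <- as.matrix(Matrix::tcrossprod(Matrix::Diagonal(x = inv) %*% M))
  dimnames(S) <- list(rownames(M), rownames(M))
  S
}

# mean of S over pairs of distinct rows between (or within) modules
pool_means <- function(S, memb) {
  mods <- sort(unique(memb))
  k <- length(mods)
  means <- matrix(NA_real_, k, k, dimnames = list(mods, mods))
  idx <- split(seq_along(memb), memb)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ri <- idx[[as.character(mods[i])]]
      rj <- idx[[as.character(mods[j])]]
      if (i == j) {
        if (length(ri) > 1) {
          block <- S[ri, ri, drop = FALSE]
          means[i, i] <- sum(block[upper.tri(block)]) / n_choose2(length(ri))
        }  # singleton module: within-mean undefined, stays NA
      } else {
        means[i, j] <- means[j, i] <- mean(S[ri, rj])
      }
    }
  }
  means
}

#' Pooled within/between-module input similarity
#'
#' Mean pairwise cosine similarity of input vectors, pooled within each
#' module (over all pairs of distinct members) and between each module pair
#' (over all cross pairs). A singleton module has no within pair; its
#' diagonal cell is reported as `NA`.
#'
#' @param M input-vector matrix from [build_input_vectors()].
#' @param p a [partition()] covering `M`'s rows.
#' @return List of class `pooled_similarity` with the symmetric `means`
#'   matrix (module x module); `z` is `NULL` until [shuffle_zscores()] adds
#'   it.
#' @export
pooled_module_similarity <- function(M, p) {
  p <- as_partition(p)
  memb <- unclass(p)[rownames(M)]
  if (anyNA(memb)) {
    stop("partition does not cover every row of the input matrix",
         call. = FALSE)
  }
  S <- row_cosine_matrix(M)
  structure(list(means = pool_means(S, memb), z = NULL, n_shuffles = 0L),
            class = "pooled_similarity")
}

#' Shuffle-null z-scores of pooled input similarity
#'
#' Repeats the pooled-means computation under `n_shuffles` random
#' permutations of the module labels (preserving module sizes) and reports,
#' per module pair, `z = (true mean - mean of shuffled means) / sd of
#' shuffled means` with the population standard deviation over shuffles. A
#' degenerate null (sd = 0) yields `NA` with a warning.
#'
#' @inheritParams pooled_module_similarity
#' @param n_shuffles number of label shuffles, `>= 2` (default 100).
#' @param seed RNG seed; z matrices are deterministic per seed.
#' @return `pooled_similarity` list with `means`, `z`, `n_shuffles`, and
#'   `null_mean` / `null_sd` matrices.
#' @export
shuffle_zscores <- function(M, p, n_shuffles = 100, seed = 1) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2", call. = FALSE)
  p <- as_partition(p)
  memb <- unclass(p)[rownames(M)]
  if (anyNA(memb)) {
    stop("partition does not cover every row of the input matrix",
         call. = FALSE)
  }
  S <- row_cosine_matrix(M)
  true_means <- pool_means(S, memb)
  sims <- with_seed(seed, lapply(seq_len(n_shuffles), function(i) {
    pool_means(S, sample(memb))
  }))
  arr <- simplify2array(sims)
  null_mean <- apply(arr, c(1, 2), mean)
  null_sd <- apply(arr, c(1, 2), function(v) {
    sqrt(mean((v - mean(v))^2))  # population sd over the shuffled means
  })
  z <- (true_means - null_mean) / null_sd
  z[null_sd == 0] <- NA_real_
  if (any(null_sd == 0, na.rm = TRUE)) {
    warning("degenerate shuffle null (sd = 0) for some module pairs; ",
            "z reported as NA")
  }
  structure(list(means = true_means, z = z, n_shuffles = n_shuffles,
                 null_mean = null_mean, null_sd = null_sd),
            class = "pooled_similarity")
}
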