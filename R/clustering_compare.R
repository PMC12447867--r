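# Comparison of partitions: pairwise co-membership Jaccard similarity,
# joint-proportion matrices, multi-run consistency of the clustering, and
# size-preserving shuffled-label baselines.

# align two partitions on their common node universe
align_pair <- function(a, b, min_nodes = 2) {
  a <- as_partition(a); b <- as_partition(b)
  common <- intersect(names(a), names(b))
  n_drop <- length(union(names(a), names(b))) - length(common)
  if (length(common) < min_nodes) {
    stop("common node universe has fewer than ", min_nodes, " nodes",
         call. = FALSE)
  }
  if (n_drop > 0) {
    message("comparison restricted to ", length(common),
            " common nodes (", n_drop, " dropped)")
  }
  list(a = unclass(a)[common], b = unclass(b)[common], ids = common)
}

n_choose2 <- function(x) x * (x - 1) / 2

#' Co-membership Jaccard similarity of two clusterings
#'
#' Over all unordered node pairs of the common universe: the number of pairs
#' co-clustered in both partitions divided by the number co-clustered in
#' either. Ranges from 0 (no overlap) to 1 (perfect overlap). When both
#' partitions are all-singletons (no co-clustered pair anywhere) the
#' clusterings are identical and the value is defined as 1.
#'
#' @param a,b [partition()]s; comparison is restricted to the intersection of
#'   their node sets (at least 2 nodes), with a message when nodes are
#'   dropped.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  pr <- align_pair(a, b)
  tab <- table(pr$a, pr$b)
  both <- sum(n_choose2(tab))
  pa <- sum(n_choose2(rowSums(tab)))
  pb <- sum(n_choose2(colSums(tab)))
  union <- pa + pb - both
  if (union == 0) return(1)  # both all-singletons: identical clusterings
  both / union
}

#' Joint-proportion matrix of two clusterings
#'
#' Counts `N[i, j]` of nodes jointly in module `i` of `a` and module `j` of
#' `b`, with the two normalizations used for joint clustering plots: the box
#' width `N[i, j] / N_b[j]` (column proportions) and height
#' `N[i, j] / N_a[i]` (row proportions).
#'
#' @inheritParams jaccard_similarity
#' @return List of class `joint_proportions` with matrices `counts`, `width`,
#'   `height` (rows: modules of `a`; columns: modules of `b`).
#' @export
joint_proportions <- function(a, b) {
  pr <- align_pair(a, b)
  counts <- unclass(table(pr$a, pr$b))
  width <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  height <- sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  structure(list(counts = counts, width = width, height = height),
            class = "joint_proportions")
}

#' Multi-run consistency of the ensemble clustering
#'
#' Runs [reneel_maximize()] `n_runs` times with seeds derived from
#' `master_seed` and summarizes agreement as the mean pairwise co-membership
#' Jaccard over all run pairs.
#'
#' @param g a [ugraph()].
#' @param chi resolution exponent.
#' @param n_runs number of runs, `>= 2`.
#' @param master_seed seed from which per-run seeds are drawn.
#' @param ensemble_size passed to [reneel_maximize()].
#' @return List with `mean_jaccard`, `pairwise` (vector over run pairs), and
#'   `partitions`.
#' @export
run_consistency <- function(g, chi = 0, n_runs = 10, master_seed = 1,
                            ensemble_size = 20) {
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max - 1, n_runs))
  parts <- lapply(seeds, function(s) {
    reneel_maximize(g, chi = chi, ensemble_size = ensemble_size,
                    seed = s)$partition
  })
  idx <- utils::combn(n_runs, 2)
  pv <- apply(idx, 2, function(ij) {
    jaccard_similarity(parts[[ij[1]]], parts[[ij[2]]])
  })
  list(mean_jaccard = mean(pv), pairwise = pv, partitions = parts)
}

#' Shuffled-label Jaccard baseline
#'
#' Randomly permutes the module labels of `a` over its nodes (preserving
#' module sizes) `n_shuffles` times and reports the distribution of Jaccard
#' similarity against `b` -- the chance level against which the observed
#' similarity of two clusterings is judged.
#'
#' @inheritParams jaccard_similarity
#' @param n_shuffles number of label permutations, `>= 1`.
#' @param seed RNG seed (deterministic summaries for a fixed seed).
#' @return List with `mean`, `sd`, `values`, and `observed` (the unshuffled
#'   Jaccard).
#' @export
shuffled_jaccard_baseline <- function(a, b, n_shuffles = 100, seed = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  pr <- align_pair(a, b)
  observed <- jaccard_similarity(partition(pr$ids, pr$a),
                                 partition(pr$ids, pr$b))
  values <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    jaccard_similarity(partition(pr$ids, sample(pr$a)),
                       partition(pr$ids, pr$b))
  }, numeric(1)))
  list(mean = mean(values), sd = stats::sd(values), values = values,
       observed = observed)
}
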