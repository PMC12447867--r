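# Brain-wide hub statistics: synaptic-endowment rankings, unique partner and
# partner cell-type counts, primacy of a target among a cell type's outputs,
# reciprocity classification, and circuit input/output ratios.

#' Rank neurons by total synaptic connections
#'
#' Orders neurons by input weight (postsynaptic densities on the neuron) plus
#' output weight, descending, with ties broken by ascending bodyId. The
#' caller is expected to have already restricted to traced, non-cropped
#' neurons and applied any weight threshold ([filter_by_weight()]).
#'
#' @param x a [connectome()].
#' @param top_n number of entries to return.
#' @return data.frame with columns `bodyId`, `label` (instance, falling back
#'   to type), `input_weight`, `output_weight`, `total_weight`, ordered by
#'   rank.
#' @export
rank_by_total_synapses <- function(x, top_n) {
  stopifnot(inherits(x, "connectome"))
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1) {
    stop("top_n must be a single integer >= 1", call. = FALSE)
  }
  ids <- x$neurons$bodyId
  if (length(ids) == 0) {
    return(data.frame(bodyId = numeric(0), label = character(0),
                      input_weight = numeric(0), output_weight = numeric(0),
                      total_weight = numeric(0)))
  }
  e <- x$edges
  inw <- outw <- stats::setNames(numeric(length(ids)), as.character(ids))
  if (nrow(e) > 0) {
    s <- tapply(e$weight, as.character(e$bodyId_post), sum)
    inw[names(s)] <- s
    s <- tapply(e$weight, as.character(e$bodyId_pre), sum)
    outw[names(s)] <- s
  }
  lab <- ifelse(is.na(x$neurons$instance), x$neurons$type, x$neurons$instance)
  d <- data.frame(bodyId = ids, label = lab, input_weight = unname(inw),
                  output_weight = unname(outw))
  d$total_weight <- d$input_weight + d$output_weight
  d <- d[order(-d$total_weight, d$bodyId), , drop = FALSE]
  d <- utils::head(d, top_n)
  rownames(d) <- NULL
  d
}

# directed pair totals >= threshold, split into partners pre/post of n
partner_sets <- function(x, n, threshold) {
  pt <- pair_totals(x)
  pt <- pt[pt$total >= threshold, , drop = FALSE]
  list(pre = unique(pt$bodyId_pre[pt$bodyId_post == n]),
       post = unique(pt$bodyId_post[pt$bodyId_pre == n]))
}

#' Count unique synaptic partners of a neuron
#'
#' Classifies each partner making a directed pair connection of total weight
#' `>= threshold` as exclusively presynaptic, exclusively postsynaptic, or
#' both.
#'
#' @param x a [connectome()].
#' @param n bodyId of the neuron.
#' @param threshold per-pair weight threshold (default 3, the conventional
#'   cutoff below which connections are considered potentially erroneous).
#' @return List with `pre_only`, `post_only`, `both`, `total`.
#' @export
count_unique_partners <- function(x, n, threshold = 3) {
  stopifnot(inherits(x, "connectome"))
  if (!n %in% x$neurons$bodyId) stop("unknown bodyId: ", n, call. = FALSE)
  ps <- partner_sets(x, n, threshold)
  b <- intersect(ps$pre, ps$post)
  list(pre_only = length(setdiff(ps$pre, b)),
       post_only = length(setdiff(ps$post, b)),
       both = length(b),
       total = length(union(ps$pre, ps$post)))
}

#' Count distinct cell types among a neuron's partners
#'
#' As [count_unique_partners()] but deduplicated at the cell-type level.
#' Partners without a cell type are excluded by default (the convention for
#' uncharacterized, `"None"`-labeled neurons); set `include_untyped = TRUE`
#' to pool them under a single `"untyped"` pseudo-type.
#'
#' @inheritParams count_unique_partners
#' @param include_untyped pool untyped partners as one pseudo-type instead of
#'   excluding them.
#' @return List with `pre_only`, `post_only`, `both`, `total` over cell
#'   types.
#' @export
count_partner_celltypes <- function(x, n, threshold = 3,
                                    include_untyped = FALSE) {
  stopifnot(inherits(x, "connectome"))
  if (!n %in% x$neurons$bodyId) stop("unknown bodyId: ", n, call. = FALSE)
  ps <- partner_sets(x, n, threshold)
  typ <- stats::setNames(x$neurons$type, as.character(x$neurons$bodyId))
  to_types <- function(ids) {
    t <- unname(typ[as.character(ids)])
    if (include_untyped) t[is.na(t)] <- "untyped" else t <- t[!is.na(t)]
    unique(t)
  }
  pre_t <- to_types(ps$pre)
  post_t <- to_types(ps$post)
  b <- intersect(pre_t, post_t)
  list(pre_only = length(setdiff(pre_t, b)),
       post_only = length(setdiff(post_t, b)),
       both = length(b),
       total = length(union(pre_t, post_t)))
}

#' Median partner cell-type count over all neurons
#'
#' For every neuron in the connectome, counts the distinct cell types among
#' its thresholded partners (both directions, untyped partners excluded) and
#' returns the median (mean of the central pair for even counts).
#'
#' @inheritParams count_unique_partners
#' @return Scalar median.
#' @export
median_partner_celltype_count <- function(x, threshold = 3) {
  stopifnot(inherits(x, "connectome"))
  if (nrow(x$neurons) == 0) stop("empty connectome", call. = FALSE)
  pt <- pair_totals(x)
  pt <- pt[pt$total >= threshold, , drop = FALSE]
  typ <- stats::setNames(x$neurons$type, as.character(x$neurons$bodyId))
  # (neuron, partner) incidences in both directions
  neuron <- c(pt$bodyId_post, pt$bodyId_pre)
  partner <- c(pt$bodyId_pre, pt$bodyId_post)
  ptype <- unname(typ[as.character(partner)])
  keep <- !is.na(ptype)
  key <- paste(neuron[keep], ptype[keep], sep = "\r")
  first <- !duplicated(key)
  counts <- table(as.character(neuron[keep][first]))
  per_neuron <- stats::setNames(numeric(nrow(x$neurons)),
                                as.character(x$neurons$bodyId))
  per_neuron[names(counts)] <- as.numeric(counts)
  stats::median(per_neuron)
}

#' Primacy of a target cell type among a source type's outputs
#'
#' Aggregates the synaptic outputs of all neurons of `source_type` by
#' postsynaptic cell type and ranks the target among them (descending
#' aggregated weight). The source type is a primary input to the target when
#' the target holds the first position, i.e. no other postsynaptic type
#' receives strictly more weight (a tie for the top does not demote). It is a
#' strong input when the aggregated weight reaches `strong_threshold`.
#'
#' @param x a [connectome()].
#' @param source_type cell type whose outputs are aggregated.
#' @param target_type cell type whose rank is assessed.
#' @param strong_threshold aggregated-weight cutoff for a strong input
#'   (default 100).
#' @param include_untyped pool untyped postsynaptic neurons under one
#'   `"untyped"` sink label so their weight can outrank the target (default);
#'   `FALSE` ignores them.
#' @return List with `cell_type`, `weight_to_target`, `target_rank`,
#'   `is_primary`, `is_strong`.
#' @export
compute_primacy <- function(x, source_type, target_type,
                            strong_threshold = 100, include_untyped = TRUE) {
  stopifnot(inherits(x, "connectome"))
  src <- x$neurons$bodyId[!is.na(x$neurons$type) &
                            x$neurons$type == source_type]
  if (length(src) == 0) {
    stop("unknown source cell type: ", source_type, call. = FALSE)
  }
  typ <- stats::setNames(x$neurons$type, as.character(x$neurons$bodyId))
  e <- x$edges[x$edges$bodyId_pre %in% src, , drop = FALSE]
  ptype <- unname(typ[as.character(e$bodyId_post)])
  if (include_untyped) ptype[is.na(ptype)] <- "untyped"
  keep <- !is.na(ptype)
  agg <- tapply(e$weight[keep], ptype[keep], sum)
  w_t <- if (target_type %in% names(agg)) unname(agg[target_type]) else 0
  others <- agg[names(agg) != target_type]
  rank <- 1 + sum(others > w_t)
  list(cell_type = source_type,
       weight_to_target = w_t,
       target_rank = rank,
       is_primary = rank == 1,
       is_strong = w_t >= strong_threshold)
}

#' Primacy table for every cell type presynaptic to a target neuron
#'
#' Convenience wrapper running [compute_primacy()] for each typed cell type
#' with at least one edge onto `target`, against the target's own cell type.
#'
#' @param x a [connectome()].
#' @param target bodyId of the target neuron (must have a cell type).
#' @param strong_threshold,include_untyped passed to [compute_primacy()].
#' @return data.frame with one row per presynaptic cell type.
#' @export
primacy_table <- function(x, target, strong_threshold = 100,
                          include_untyped = TRUE) {
  stopifnot(inherits(x, "connectome"))
  if (!target %in% x$neurons$bodyId) {
    stop("unknown target bodyId: ", target, call. = FALSE)
  }
  typ <- stats::setNames(x$neurons$type, as.character(x$neurons$bodyId))
  target_type <- unname(typ[as.character(target)])
  if (is.na(target_type)) stop("target neuron has no cell type", call. = FALSE)
  pre <- unique(x$edges$bodyId_pre[x$edges$bodyId_post == target])
  src_types <- sort(unique(stats::na.omit(unname(typ[as.character(pre)]))))
  rows <- lapply(src_types, function(tt) {
    as.data.frame(compute_primacy(x, tt, target_type,
                                  strong_threshold = strong_threshold,
                                  include_untyped = include_untyped))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a reciprocal connection
#'
#' A pair of neurons (or cell types) is highly reciprocal when both
#' directions carry weight and the stronger direction is no more than twice
#' the weaker one.
#'
#' @param weight_to_target,weight_from_target non-negative weights of the two
#'   directions.
#' @return `TRUE` iff both weights are positive and their ratio is at most 2.
#' @export
classify_reciprocity <- function(weight_to_target, weight_from_target) {
  stopifnot(weight_to_target >= 0, weight_from_target >= 0)
  if (weight_to_target <= 0 || weight_from_target <= 0) return(FALSE)
  max(weight_to_target, weight_from_target) /
    min(weight_to_target, weight_from_target) <= 2
}

#' Circuit input/output ratios of a neuron
#'
#' Proportion of a neuron's input (output) synapse weight exchanged with a
#' designated circuit: weight from circuit members onto `n` over weight from
#' all presynaptic partners, and analogously for outputs. Pairs below
#' `threshold` are excluded; an empty denominator yields 0.
#'
#' @param x a [connectome()].
#' @param circuit_ids bodyIds of the circuit members (`n` itself allowed).
#' @param n bodyId of the focal neuron.
#' @param threshold per-pair weight threshold (default 3).
#' @return List with `input_ratio` and `output_ratio`.
#' @export
circuit_io_ratio <- function(x, circuit_ids, n, threshold = 3) {
  stopifnot(inherits(x, "connectome"))
  if (!n %in% x$neurons$bodyId) stop("unknown bodyId: ", n, call. = FALSE)
  pt <- pair_totals(x)
  pt <- pt[pt$total >= threshold, , drop = FALSE]
  inc <- pt[pt$bodyId_post == n & pt$bodyId_pre != n, , drop = FALSE]
  out <- pt[pt$bodyId_pre == n & pt$bodyId_post != n, , drop = FALSE]
  ratio <- function(part, whole) if (whole > 0) part / whole else 0
  list(input_ratio = ratio(sum(inc$total[inc$bodyId_pre %in% circuit_ids]),
                           sum(inc$total)),
       output_ratio = ratio(sum(out$total[out$bodyId_post %in% circuit_ids]),
                            sum(out$total)))
}
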