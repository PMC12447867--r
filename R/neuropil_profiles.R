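# Per-module synapse localization by neuropil supercategory, and
# module-annotated synapse-site export.

profile_matrix <- function(module, supercat, weight) {
  cats <- c(SUPERCATEGORIES, "NotPrimary")
  mods <- sort(unique(module))
  out <- matrix(0, length(mods), length(cats), dimnames = list(mods, cats))
  s <- tapply(weight, list(module, supercat), sum)
  out[rownames(s), colnames(s)] <- ifelse(is.na(s), 0, s)
  out
}

#' Supercategory profile of inputs onto a target neuron
#'
#' Sums the synapse weights of edges from each module's neurons onto the
#' target within each neuropil supercategory. Edges whose ROI is absent or
#' unrecognized count under `"NotPrimary"`; presynaptic neurons not covered
#' by the partition are pooled under an `"unassigned"` module row.
#'
#' @param x a [connectome()].
#' @param target bodyId of the target neuron.
#' @param p a [partition()] over (at least) the target's presynaptic
#'   partners.
#' @param m a [load_roi_map()] table.
#' @return Matrix (module x supercategory) of summed synapse weights.
#' @export
target_input_profile <- function(x, target, p, m = load_roi_map()) {
  stopifnot(inherits(x, "connectome"))
  if (!target %in% x$neurons$bodyId) {
    stop("unknown target bodyId: ", target, call. = FALSE)
  }
  p <- as_partition(p)
  e <- x$edges[x$edges$bodyId_post == target, , drop = FALSE]
  module <- unclass(p)[as.character(e$bodyId_pre)]
  module[is.na(module)] <- "unassigned"
  profile_matrix(module, map_roi_supercategory(e$roi, m), e$weight)
}

#' Supercategory profile of all inputs to each module's members
#'
#' For every module, sums the synapse weights of all edges in the connectome
#' onto that module's member neurons, by neuropil supercategory. Unlike the
#' input-similarity stage, inputs arriving from other subconnectome members
#' are included.
#'
#' @param full a [connectome()].
#' @param p a [partition()]; neurons outside it are ignored as recipients.
#' @param m a [load_roi_map()] table.
#' @return Matrix (module x supercategory) of summed synapse weights.
#' @export
module_member_input_profile <- function(full, p, m = load_roi_map()) {
  stopifnot(inherits(full, "connectome"))
  p <- as_partition(p)
  e <- full$edges
  module <- unclass(p)[as.character(e$bodyId_post)]
  keep <- !is.na(module)
  profile_matrix(module[keep], map_roi_supercategory(e$roi[keep], m),
                 e$weight[keep])
}

#' Annotate synapse sites with the presynaptic neuron's module
#'
#' Joins module labels onto a synapse-site table (3D location, presynaptic
#' and postsynaptic bodyIds referring to a single target) by `pre_id`.
#' Sites from neurons absent from the partition are labeled `"unassigned"`,
#' or dropped when `drop_unassigned = TRUE` (drop count in the
#' `dropped_sites` attribute).
#'
#' @param sites data.frame with columns `x`, `y`, `z`, `pre_id`, `post_id`.
#' @param p a [partition()].
#' @param drop_unassigned drop sites whose presynaptic neuron has no module.
#' @return The site table with a `module` column appended.
#' @export
annotate_synapse_sites <- function(sites, p, drop_unassigned = FALSE) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("x", "y", "z", "pre_id", "post_id") %in% names(sites)))
  if (length(unique(sites$post_id)) > 1) {
    stop("site table must reference a single target post_id", call. = FALSE)
  }
  p <- as_partition(p)
  module <- unclass(p)[as.character(sites$pre_id)]
  unass <- is.na(module)
  module[unass] <- "unassigned"
  sites$module <- module
  n_drop <- 0L
  if (drop_unassigned && any(unass)) {
    n_drop <- sum(unass)
    sites <- sites[!unass, , drop = FALSE]
    rownames(sites) <- NULL
  }
  attr(sites, "dropped_sites") <- n_drop
  sites
}
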