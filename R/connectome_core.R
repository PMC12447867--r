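# Core containers and table I/O for connectome analysis.
#
# A connectome is a pair of plain data.frames mirroring the neuprint-style
# exports: a neuron annotation table (bodyId, type, instance, traced, cropped)
# and a directed, ROI-labeled adjacency table (bodyId_pre, bodyId_post, roi,
# weight) where weight counts postsynaptic densities.

SUPERCATEGORIES <- c("OL", "MB", "LH", "SNP", "INP", "AL",
                     "VMNP", "VLNP", "LX", "CX", "PENP", "GNG")

#' Construct and validate a connectome
#'
#' Bundles a neuron annotation table and a directed weighted edge table into a
#' validated `connectome` object. Self-loops (autapses) are removed, duplicate
#' `(pre, post, roi)` rows are summed, and edges whose endpoints are absent
#' from the neuron table are either dropped with a count (lenient, the
#' default) or rejected (strict).
#'
#' @param neurons data.frame with columns `bodyId` (unique), `type`,
#'   `instance` (both may be `NA` for uncharacterized neurons), `traced`,
#'   `cropped` (logicals).
#' @param edges data.frame with columns `bodyId_pre`, `bodyId_post`, `weight`
#'   (positive integers) and optionally `roi` (primary neuropil of the
#'   connection, `NA` when unlocalized).
#' @param strict if `TRUE`, edges referencing unknown neurons are an error;
#'   otherwise they are dropped and counted in the `dropped_edges` attribute.
#' @return An object of class `connectome`: a list with elements `neurons`
#'   and `edges`. Attributes `dropped_edges` and `self_loops_removed` record
#'   what validation discarded.
#' @export
connectome <- function(neurons, edges, strict = FALSE) {
  neurons <- as.data.frame(neurons)
  edges <- as.data.frame(edges)
  for (col in c("bodyId", "type", "instance", "traced", "cropped")) {
    if (!col %in% names(neurons)) {
      stop("neuron table is missing required column '", col, "'", call. = FALSE)
    }
  }
  for (col in c("bodyId_pre", "bodyId_post", "weight")) {
    if (!col %in% names(edges)) {
      stop("edge table is missing required column '", col, "'", call. = FALSE)
    }
  }
  if (!"roi" %in% names(edges)) edges$roi <- NA_character_
  if (anyDuplicated(neurons$bodyId)) {
    stop("duplicate bodyId in neuron table", call. = FALSE)
  }
  bad <- which(!is.finite(edges$weight) | edges$weight != round(edges$weight) |
                 edges$weight < 1)
  if (length(bad) > 0) {
    stop("edge weight must be a positive integer; first violation at row ",
         bad[1], " (weight = ", edges$weight[bad[1]], ")", call. = FALSE)
  }

  suffixed <- !is.na(neurons$instance) & grepl("_[RL]$", neurons$instance)
  neurons$instance <- as.character(neurons$instance)
  neurons$type <- as.character(neurons$type)

  self <- edges$bodyId_pre == edges$bodyId_post
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]

  known <- edges$bodyId_pre %in% neurons$bodyId &
    edges$bodyId_post %in% neurons$bodyId
  n_drop <- sum(!known)
  if (n_drop > 0) {
    if (strict) {
      stop(n_drop, " edge(s) reference bodyIds absent from the neuron table",
           call. = FALSE)
    }
    message("dropped ", n_drop, " edge(s) referencing unknown neurons")
    edges <- edges[known, , drop = FALSE]
  }

  # collapse duplicate (pre, post, roi) rows by summing weight
  key <- paste(edges$bodyId_pre, edges$bodyId_post, edges$roi, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, sum)
    first <- edges[!duplicated(key), , drop = FALSE]
    first$weight <- as.numeric(w[paste(first$bodyId_pre, first$bodyId_post,
                                       first$roi, sep = "\r")])
    edges <- first
  }
  rownames(edges) <- NULL
  rownames(neurons) <- NULL

  structure(
    list(neurons = neurons[, c("bodyId", "type", "instance", "traced", "cropped")],
         edges = edges[, c("bodyId_pre", "bodyId_post", "roi", "weight")]),
    dropped_edges = n_drop,
    self_loops_removed = n_self,
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$neurons), " neurons, ", nrow(x$edges),
      " edge rows (total weight ", sum(x$edges$weight), ")\n", sep = "")
  invisible(x)
}

#' Load a connectome from neuron and adjacency tables
#'
#' Reads the comma-separated neuron annotation and adjacency tables of a
#' traced-adjacencies style export. The neuron table must carry `bodyId`,
#' `type`, `instance` and either logical `traced`/`cropped` columns or a
#' `status` column (rows whose status equals `"Traced"` are taken as traced;
#' a `cropped` column is honored when present, otherwise neurons are assumed
#' uncropped, matching exports that contain only uncropped bodies).
#'
#' @param neuron_table_path,edge_table_path paths to CSV files with a header
#'   row.
#' @param strict passed to [connectome()].
#' @return A validated [connectome()].
#' @export
load_connectome <- function(neuron_table_path, edge_table_path, strict = FALSE) {
  if (!file.exists(neuron_table_path)) {
    stop("neuron table not found: ", neuron_table_path, call. = FALSE)
  }
  if (!file.exists(edge_table_path)) {
    stop("edge table not found: ", edge_table_path, call. = FALSE)
  }
  neurons <- utils::read.csv(neuron_table_path, stringsAsFactors = FALSE,
                             na.strings = c("NA", "", "None"))
  edges <- utils::read.csv(edge_table_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!"bodyId" %in% names(neurons)) {
    stop("neuron table is missing required column 'bodyId'", call. = FALSE)
  }
  if (!"type" %in% names(neurons)) neurons$type <- NA_character_
  if (!"instance" %in% names(neurons)) neurons$instance <- NA_character_
  if (!"traced" %in% names(neurons)) {
    if ("status" %in% names(neurons)) {
      neurons$traced <- !is.na(neurons$status) & neurons$status == "Traced"
    } else {
      stop("neuron table is missing required column 'traced' (or 'status')",
           call. = FALSE)
    }
  }
  if (!"cropped" %in% names(neurons)) neurons$cropped <- FALSE
  neurons$traced <- as.logical(neurons$traced)
  neurons$cropped <- as.logical(neurons$cropped)
  if (is.character(edges$weight)) {
    wnum <- suppressWarnings(as.numeric(edges$weight))
    bad <- which(is.na(wnum) & !is.na(edges$weight))
    if (length(bad) > 0) {
      stop("non-numeric weight '", edges$weight[bad[1]], "' at edge table row ",
           bad[1], call. = FALSE)
    }
    edges$weight <- wnum
  }
  connectome(neurons, edges, strict = strict)
}

#' Write a connectome back to neuron and adjacency CSV tables
#'
#' Inverse of [load_connectome()]: round-trips every
#' `(pre, post, roi, weight)` record.
#'
#' @param x a [connectome()].
#' @param neuron_table_path,edge_table_path output CSV paths.
#' @export
write_connectome <- function(x, neuron_table_path, edge_table_path) {
  stopifnot(inherits(x, "connectome"))
  utils::write.csv(x$neurons, neuron_table_path, row.names = FALSE, na = "")
  utils::write.csv(x$edges, edge_table_path, row.names = FALSE, na = "")
  invisible(x)
}

# per-direction pair totals, summed over roi rows
pair_totals <- function(x) {
  e <- x$edges
  key <- paste(e$bodyId_pre, e$bodyId_post, sep = "\r")
  tot <- tapply(e$weight, key, sum)
  first <- !duplicated(key)
  data.frame(bodyId_pre = e$bodyId_pre[first],
             bodyId_post = e$bodyId_post[first],
             total = as.numeric(tot[key[first]]))
}

#' Filter a connectome by per-pair connection weight
#'
#' Drops every directed neuron pair whose total connection weight (summed
#' over ROI-split rows) falls below `threshold`. The ROI split of retained
#' pairs is preserved. Weak pairs (weight below 3 in the Hemibrain) are
#' flagged as potentially erroneous connections, hence the conventional
#' default threshold of 3 used by the ranking analyses.
#'
#' @param x a [connectome()].
#' @param threshold positive integer; pairs with total weight `>= threshold`
#'   are kept.
#' @return A filtered [connectome()].
#' @export
filter_by_weight <- function(x, threshold) {
  stopifnot(inherits(x, "connectome"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    stop("threshold must be a single integer >= 1", call. = FALSE)
  }
  if (threshold == 1) return(x)
  e <- x$edges
  key <- paste(e$bodyId_pre, e$bodyId_post, sep = "\r")
  tot <- tapply(e$weight, key, sum)
  keep <- tot[key] >= threshold
  out <- x
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Restrict a connectome to traced, non-cropped neurons
#'
#' @param x a [connectome()].
#' @return A [connectome()] keeping only neurons with `traced = TRUE` and
#'   `cropped = FALSE`, and the edges among them.
#' @export
restrict_traced_uncropped <- function(x) {
  stopifnot(inherits(x, "connectome"))
  keep <- x$neurons$traced & !x$neurons$cropped
  ids <- x$neurons$bodyId[keep]
  out <- x
  out$neurons <- x$neurons[keep, , drop = FALSE]
  sel <- x$edges$bodyId_pre %in% ids & x$edges$bodyId_post %in% ids
  out$edges <- x$edges[sel, , drop = FALSE]
  rownames(out$neurons) <- NULL
  rownames(out$edges) <- NULL
  out
}

#' Extract the input subconnectome of a target neuron
#'
#' Returns the induced network on all presynaptic partners of `target`: every
#' neuron with at least one edge of any weight onto the target (no weight
#' threshold is applied, so weak partners are deliberately retained), plus all
#' edges of `x` among those partners. The target itself is excluded.
#'
#' @param x a [connectome()].
#' @param target bodyId present in `x`.
#' @return A [connectome()] on the presynaptic partner set.
#' @export
extract_input_subconnectome <- function(x, target) {
  stopifnot(inherits(x, "connectome"))
  if (!target %in% x$neurons$bodyId) {
    stop("unknown target bodyId: ", target, call. = FALSE)
  }
  partners <- unique(x$edges$bodyId_pre[x$edges$bodyId_post == target])
  partners <- setdiff(partners, target)
  out <- x
  out$neurons <- x$neurons[x$neurons$bodyId %in% partners, , drop = FALSE]
  sel <- x$edges$bodyId_pre %in% partners & x$edges$bodyId_post %in% partners
  out$edges <- x$edges[sel, , drop = FALSE]
  rownames(out$neurons) <- NULL
  rownames(out$edges) <- NULL
  out
}

#' Undirected weighted graph
#'
#' Light container used by the clustering stage. Nodes may carry `size`
#' (member count) and `internal` (internal weight) annotations so that a
#' reduced graph produced by [reduce_graph()] can be scored exactly as its
#' expansion on the original graph.
#'
#' @param edges data.frame with columns `u`, `v`, `weight` (one row per
#'   unordered pair; `u != v`, positive weights). Duplicate pairs are summed.
#' @param nodes optional data.frame with columns `id`, `size`, `internal`;
#'   defaults to the ids occurring in `edges` with size 1 and internal 0.
#' @return An object of class `ugraph`.
#' @export
ugraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("u", "v", "weight") %in% names(edges)))
  if (any(edges$u == edges$v)) stop("self-pairs are not allowed", call. = FALSE)
  if (any(edges$weight <= 0)) stop("weights must be positive", call. = FALSE)
  # canonical unordered order
  u <- pmin(edges$u, edges$v)
  v <- pmax(edges$u, edges$v)
  key <- paste(u, v, sep = "\r")
  w <- tapply(edges$weight, key, sum)
  first <- !duplicated(key)
  edges <- data.frame(u = u[first], v = v[first],
                      weight = as.numeric(w[key[first]]))
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$u, edges$v)))
    nodes <- data.frame(id = ids, size = 1L, internal = 0)
  } else {
    nodes <- as.data.frame(nodes)
    stopifnot("id" %in% names(nodes))
    if (!"size" %in% names(nodes)) nodes$size <- 1L
    if (!"internal" %in% names(nodes)) nodes$internal <- 0
    if (!all(c(edges$u, edges$v) %in% nodes$id)) {
      stop("edge endpoints missing from node table", call. = FALSE)
    }
  }
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes[, c("id", "size", "internal")], edges = edges),
            class = "ugraph")
}

#' @export
print.ugraph <- function(x, ...) {
  cat("<ugraph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (total weight ", sum(x$edges$weight) + sum(x$nodes$internal),
      ")\n", sep = "")
  invisible(x)
}

#' Symmetrize a directed connectome into an undirected weighted graph
#'
#' The weight of an undirected pair is the total synaptic weight between the
#' two neurons in both directions (summed over ROIs). Self-loops contribute
#' nothing. Neurons with no surviving pair still appear as isolated nodes.
#'
#' @param x a [connectome()].
#' @return A [ugraph()] whose node set is the neuron set of `x`.
#' @export
to_undirected <- function(x) {
  stopifnot(inherits(x, "connectome"))
  e <- x$edges
  nodes <- data.frame(id = sort(x$neurons$bodyId), size = 1L, internal = 0)
  if (nrow(e) == 0) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(u = numeric(0), v = numeric(0),
                                             weight = numeric(0))),
                     class = "ugraph"))
  }
  ugraph(data.frame(u = e$bodyId_pre, v = e$bodyId_post, weight = e$weight),
         nodes = nodes)
}

#' Load the primary-neuropil to supercategory map
#'
#' The packaged table maps each Hemibrain primary neuropil to one of the 12
#' canonical supercategories of the standard insect-brain nomenclature (OL,
#' MB, LH, SNP, INP, AL, VMNP, VLNP, LX, CX, PENP, GNG). The shipped file is
#' reconstructed from that standard nomenclature (e.g. SLP/SIP/SMP roll up
#' into SNP; FB/EB/PB/NO/AB into CX).
#'
#' @param path optional path to a two-column CSV (`primary_roi`,
#'   `supercategory`); defaults to the packaged table.
#' @return A data.frame of class `roi_map`.
#' @export
load_roi_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "roi_supercategories.csv",
                        package = "connhub", mustWork = TRUE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("primary_roi", "supercategory") %in% names(m)))
  bad <- setdiff(unique(m$supercategory), c(SUPERCATEGORIES, "NotPrimary"))
  if (length(bad) > 0) {
    stop("unknown supercategory in roi map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(m) <- c("roi_map", "data.frame")
  m
}

# strip a trailing laterality marker: "SMP(R)" -> "SMP", "SLP_L" -> "SLP"
strip_laterality <- function(roi) {
  sub("(\\(R\\)|\\(L\\)|_R|_L)$", "", roi)
}

#' Map primary neuropils to their supercategory
#'
#' Right/left variants of the same neuropil (`"SMP(R)"`, `"SMP(L)"`,
#' `"SMP_R"`) map to one supercategory. Absent (`NA`) or unrecognized ROIs
#' map to `"NotPrimary"`, the bucket for synapses falling outside the primary
#' neuropils.
#'
#' @param roi character vector of primary neuropil names (may contain `NA`).
#' @param m a [load_roi_map()] table.
#' @return Character vector of supercategory names.
#' @export
map_roi_supercategory <- function(roi, m = load_roi_map()) {
  stopifnot(inherits(m, "roi_map"))
  base <- strip_laterality(as.character(roi))
  out <- m$supercategory[match(base, m$primary_roi)]
  out[is.na(out)] <- "NotPrimary"
  out
}
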