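# Synthetic connectomes with planted structure: modular Erdos-Renyi blocks
# with geometric integer weights, a hub neuron receiving inputs from every
# module, contiguous cell-type blocks (some spanning module boundaries),
# module-specific neuropil label distributions, and weak (< 3) noise edges.
# Every downstream stage of the pipeline is testable against the planted
# ground truth.

# representative primary neuropils per supercategory (with laterality
# variants so right/left merging is exercised)
ROI_REPRESENTATIVES <- list(
  SNP = c("SMP(R)", "SIP(R)", "SLP(R)", "SMP(L)"),
  CX = c("FB", "EB", "NO"),
  INP = c("CRE(R)", "ICL(R)", "SCL(L)"),
  LX = c("LAL(R)", "BU(R)"),
  VMNP = c("VES(R)", "SPS(R)"),
  MB = c("aL(R)", "CA(R)"),
  VLNP = c("AVLP(R)", "PLP(R)"),
  OL = c("ME(R)"),
  AL = c("AL(R)"),
  LH = c("LH(R)"),
  PENP = c("SAD"),
  GNG = c("GNG"),
  NotPrimary = NA_character_
)

default_roi_profiles <- function(k) {
  dominant <- rep(c("SNP", "CX", "INP", "LX", "VMNP", "MB", "VLNP"),
                  length.out = k)
  lapply(seq_len(k), function(j) {
    d <- dominant[j]
    if (d == "SNP") {
      c(SNP = 0.9, NotPrimary = 0.1)
    } else {
      stats::setNames(c(0.7, 0.2, 0.1), c(d, "SNP", "NotPrimary"))
    }
  })
}

#' Specification of a synthetic connectome
#'
#' Defaults describe the planted benchmark used throughout the test suite:
#' four 50-neuron modules with dense within-module (`p_within = 0.3`) and
#' sparse between-module (`p_between = 0.01`) directed connectivity, a
#' geometric weight law on \{1, 2, ...\} (heavier within modules), a hub
#' receiving inputs from 70% of every module, cell types of 3-6 neurons, and
#' weak noise edges of weight 1-2.
#'
#' @param module_sizes positive integers, neurons per planted module.
#' @param p_within,p_between directed edge probabilities inside / between
#'   modules.
#' @param weight_mean_within,weight_mean_between means (>= 1) of the
#'   geometric integer weight law for block edges.
#' @param hub_fanin_fraction fraction of each module's neurons synapsing onto
#'   the hub.
#' @param hub_weight_mean mean hub-input weight.
#' @param celltype_size_range integer (min, max) neurons per synthetic cell
#'   type.
#' @param primary_fraction fraction of hub-input cell types engineered to
#'   have the hub as their strictly strongest (and strong, >= 100) aggregate
#'   output.
#' @param roi_profiles list (one element per module) of named probability
#'   vectors over supercategory labels (including `"NotPrimary"`) from which
#'   per-edge primary-neuropil labels are drawn; `NULL` for the default
#'   module-specific profiles.
#' @param noise_edge_rate expected number of extra weight-1/2 noise edges per
#'   neuron.
#' @param seed master seed; one seeded generator drives every draw.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(module_sizes = rep(50L, 4),
                           p_within = 0.3, p_between = 0.01,
                           weight_mean_within = 8, weight_mean_between = 2,
                           hub_fanin_fraction = 0.7, hub_weight_mean = 20,
                           celltype_size_range = c(3L, 6L),
                           primary_fraction = 0.5,
                           roi_profiles = NULL,
                           noise_edge_rate = 0.5,
                           seed = 1L) {
  if (length(module_sizes) == 0 || any(module_sizes < 1)) {
    stop("module_sizes must be non-empty positive integers", call. = FALSE)
  }
  for (p in c(p_within, p_between, hub_fanin_fraction, primary_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (weight_mean_within < 1 || weight_mean_between < 1 || hub_weight_mean < 1) {
    stop("weight means must be >= 1", call. = FALSE)
  }
  if (is.null(roi_profiles)) {
    roi_profiles <- default_roi_profiles(length(module_sizes))
  }
  stopifnot(length(roi_profiles) == length(module_sizes))
  structure(list(module_sizes = as.integer(module_sizes),
                 p_within = p_within, p_between = p_between,
                 weight_mean_within = weight_mean_within,
                 weight_mean_between = weight_mean_between,
                 hub_fanin_fraction = hub_fanin_fraction,
                 hub_weight_mean = hub_weight_mean,
                 celltype_size_range = as.integer(celltype_size_range),
                 primary_fraction = primary_fraction,
                 roi_profiles = roi_profiles,
                 noise_edge_rate = noise_edge_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# geometric on {1, 2, ...} with the given mean
rgeom1 <- function(n, mean) 1 + stats::rgeom(n, prob = 1 / mean)

# directed block edges between (possibly equal) id vectors
block_edges <- function(pre_ids, post_ids, p, wmean) {
  grid <- expand.grid(pre = pre_ids, post = post_ids)
  grid <- grid[grid$pre != grid$post, , drop = FALSE]
  keep <- stats::runif(nrow(grid)) < p
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) return(NULL)
  data.frame(bodyId_pre = grid$pre, bodyId_post = grid$post,
             weight = rgeom1(nrow(grid), wmean))
}

sample_rois <- function(modules, roi_profiles) {
  vapply(modules, function(m) {
    prof <- roi_profiles[[m]]
    sc <- sample(names(prof), 1, prob = prof)
    reps <- ROI_REPRESENTATIVES[[sc]]
    if (length(reps) == 1 && is.na(reps[1])) NA_character_
    else sample(reps, 1)
  }, character(1))
}

#' Generate a synthetic connectome with planted structure
#'
#' Deterministic for a fixed `spec$seed`. Cell types are contiguous blocks
#' within modules, with the block at every module boundary fused so that some
#' types span two modules. A `primary_fraction` of the hub-input cell types
#' is engineered (by adjusting their hub edge weights after all stochastic
#' edges are placed) to have the hub as their strictly strongest aggregate
#' output with weight >= 100, while the remaining hub-input types are capped
#' below the strong threshold, so the planted primary-strong set is
#' recoverable exactly on noiseless specs.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `connectome` (a [connectome()]), and `ground_truth`: the
#'   planted [partition()] over non-hub neurons, `hub_id`, and
#'   `primary_celltypes`.
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    sizes <- spec$module_sizes
    k <- length(sizes)
    n <- sum(sizes)
    ids <- seq_len(n)
    hub_id <- n + 1L
    module <- rep(seq_len(k), sizes)

    # cell types: contiguous blocks; fuse the block at each module boundary
    type_of <- character(n)
    ct <- 0L
    i <- 1L
    boundaries <- cumsum(sizes)[-k]
    while (i <= n) {
      ct <- ct + 1L
      len <- sample(seq(spec$celltype_size_range[1],
                        spec$celltype_size_range[2]), 1)
      j <- min(n, i + len - 1L)
      # span the boundary: if the block ends exactly at a module boundary,
      # extend it into the next module by one neuron
      if (j %in% boundaries && j < n) j <- j + 1L
      type_of[i:j] <- sprintf("CT%03d", ct)
      i <- j + 1L
    }

    edges <- list()
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        p <- if (a == b) spec$p_within else spec$p_between
        wm <- if (a == b) spec$weight_mean_within else spec$weight_mean_between
        if (p > 0) {
          edges[[length(edges) + 1]] <-
            block_edges(ids[module == a], ids[module == b], p, wm)
        }
      }
    }

    # hub fan-in from every module
    hub_pre <- integer(0)
    for (a in seq_len(k)) {
      mem <- ids[module == a]
      n_in <- max(1L, round(spec$hub_fanin_fraction * length(mem)))
      hub_pre <- c(hub_pre, sort(sample(mem, n_in)))
    }
    edges[[length(edges) + 1]] <-
      data.frame(bodyId_pre = hub_pre, bodyId_post = hub_id,
                 weight = rgeom1(length(hub_pre), spec$hub_weight_mean))

    # weak noise edges (weight < 3)
    n_noise <- round(spec$noise_edge_rate * n)
    if (n_noise > 0) {
      npre <- sample(ids, n_noise, replace = TRUE)
      npost <- sample(c(ids, hub_id), n_noise, replace = TRUE)
      ok <- npre != npost
      if (any(ok)) {
        edges[[length(edges) + 1]] <-
          data.frame(bodyId_pre = npre[ok], bodyId_post = npost[ok],
                     weight = sample(1:2, sum(ok), replace = TRUE))
      }
    }

    e <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])

    # plant primacy: choose hub-input types, then adjust hub edge weights
    all_types <- c(stats::setNames(type_of, ids),
                   stats::setNames("hubIN", hub_id))
    hub_rows <- e$bodyId_post == hub_id
    hub_types <- unique(type_of[e$bodyId_pre[hub_rows]])
    n_primary <- round(spec$primary_fraction * length(hub_types))
    primary_types <- sort(sample(hub_types, n_primary))
    for (tt in hub_types) {
      members <- ids[type_of == tt]
      rows <- e$bodyId_pre %in% members
      agg <- tapply(e$weight[rows],
                    unname(all_types[as.character(e$bodyId_post[rows])]), sum)
      w_hub <- if ("hubIN" %in% names(agg)) unname(agg[["hubIN"]]) else 0
      w_other <- if (any(names(agg) != "hubIN")) {
        max(agg[names(agg) != "hubIN"])
      } else 0
      trows <- which(rows & hub_rows)
      if (tt %in% primary_types) {
        target_total <- max(w_other + 1, 100)
        if (w_hub < target_total) {
          e$weight[trows[1]] <- e$weight[trows[1]] + (target_total - w_hub)
        }
      } else if (w_hub >= 100) {
        # cap below the strong threshold so the planted set is exact
        e$weight[trows] <- pmax(1, floor(99 / length(trows)))
      }
    }

    # per-edge neuropil labels from the presynaptic neuron's module profile
    e$roi <- sample_rois(module[e$bodyId_pre], spec$roi_profiles)

    neurons <- data.frame(
      bodyId = c(ids, hub_id),
      type = c(type_of, "hubIN"),
      instance = c(paste0(type_of, "_R"), "hubIN_R"),
      traced = TRUE, cropped = FALSE)

    list(connectome = connectome(neurons, e),
         ground_truth = list(partition = partition(ids, module),
                             hub_id = hub_id,
                             primary_celltypes = primary_types))
  })
}

#' Fixed six-node worked-example graph
#'
#' Two unit-weight triangles (a-b-c and d-e-f) joined by the single bridge
#' c-d: total weight 7, degree sequence (2, 2, 3, 3, 2, 2). The optimal
#' two-triangle partition has generalized modularity density 5/14 at every
#' resolution.
#'
#' @return A [ugraph()] on nodes `a` to `f`.
#' @export
worked_example_graph <- function() {
  ugraph(data.frame(
    u = c("a", "b", "a", "d", "e", "d", "c"),
    v = c("b", "c", "c", "e", "f", "f", "d"),
    weight = 1))
}
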