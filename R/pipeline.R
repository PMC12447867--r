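# End-to-end orchestration: load -> rank -> primacy -> subconnectome ->
# cluster -> compare -> similarity -> neuropil profiles, with a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Collects the paths and parameters of a full analysis run. Defaults follow
#' the conventions used throughout the package: pair-weight threshold 3 for
#' rankings, strong-input threshold 100, coarse resolution `chi = 0`, and a
#' 100-shuffle similarity null.
#'
#' @param neuron_table,edge_table input CSV paths ([load_connectome()]).
#' @param out_dir output directory (created if missing).
#' @param target target selector: an instance label or a bodyId
#'   ([resolve_target()]).
#' @param roi_map optional path to a ROI-supercategory table; `NULL` for the
#'   packaged one.
#' @param weight_threshold per-pair weight threshold for ranking/partner
#'   stages.
#' @param strong_threshold aggregated-weight cutoff for strong inputs.
#' @param chi clustering resolution exponent.
#' @param ensemble_size RenEEL ensemble size.
#' @param n_runs consistency runs (0 disables the consistency stage; the
#'   full-scale convention is 30).
#' @param n_shuffles shuffles for the similarity null.
#' @param seed master seed for every stochastic stage.
#' @param reference_partition optional path to a partition table of a
#'   reference (e.g. full-connectome) clustering for the comparison stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(neuron_table, edge_table, out_dir, target,
                            roi_map = NULL, weight_threshold = 3,
                            strong_threshold = 100, chi = 0,
                            ensemble_size = 20, n_runs = 0,
                            n_shuffles = 100, seed = 1,
                            reference_partition = NULL) {
  req <- list(neuron_table = neuron_table, edge_table = edge_table,
              out_dir = out_dir, target = target)
  for (nm in names(req)) {
    if (is.null(req[[nm]]) || length(req[[nm]]) != 1 || is.na(req[[nm]])) {
      stop("config field '", nm, "' is required", call. = FALSE)
    }
  }
  structure(c(req, list(roi_map = roi_map,
                        weight_threshold = weight_threshold,
                        strong_threshold = strong_threshold, chi = chi,
                        ensemble_size = ensemble_size, n_runs = n_runs,
                        n_shuffles = n_shuffles, seed = seed,
                        reference_partition = reference_partition)),
            class = "pipeline_config")
}

#' Resolve a target selector to a bodyId
#'
#' @param x a [connectome()].
#' @param selector an instance label (matched exactly against the `instance`
#'   column) or a bodyId (numeric, or a string of digits).
#' @return The matched bodyId; zero or multiple matches raise an error
#'   listing the candidates.
#' @export
resolve_target <- function(x, selector) {
  stopifnot(inherits(x, "connectome"))
  if (is.numeric(selector) ||
      (is.character(selector) && grepl("^[0-9]+$", selector))) {
    id <- as.numeric(selector)
    if (!id %in% x$neurons$bodyId) {
      stop("no neuron with bodyId ", selector, call. = FALSE)
    }
    return(id)
  }
  hits <- x$neurons$bodyId[!is.na(x$neurons$instance) &
                             x$neurons$instance == selector]
  if (length(hits) == 0) {
    stop("no neuron with instance '", selector, "'", call. = FALSE)
  }
  if (length(hits) > 1) {
    stop("selector '", selector, "' matches multiple neurons: ",
         paste(hits, collapse = ", "), call. = FALSE)
  }
  hits
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = paste0("stage '", name, "' failed: ",
                                         conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Run the full hub-input analysis pipeline
#'
#' Executes all stages in order -- load and restrict to traced/uncropped
#' neurons, resolve the target, rank neurons, build the primacy/reciprocity
#' table, extract the target's input subconnectome, cluster it with RenEEL,
#' optionally compare against a reference partition and measure multi-run
#' consistency, compute pooled input similarity with shuffle-null z-scores,
#' and the neuropil supercategory profiles. All tabular outputs are written
#' as CSVs under `cfg$out_dir`, alongside a JSON manifest recording
#' parameters, seeds, and input/output digests. Re-running with an identical
#' config reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each stage and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  written <- character(0)
  save_csv <- function(d, f, rn = FALSE) {
    utils::write.csv(d, out(f), row.names = rn)
    written <<- c(written, f)
  }

  conn <- pipeline_stage("load", {
    restrict_traced_uncropped(
      load_connectome(cfg$neuron_table, cfg$edge_table))
  })
  roi_map <- pipeline_stage("roi_map", load_roi_map(cfg$roi_map))
  target <- pipeline_stage("resolve_target", resolve_target(conn, cfg$target))

  rank_tab <- pipeline_stage("rank", {
    filt <- filter_by_weight(conn, cfg$weight_threshold)
    r <- rank_by_total_synapses(filt, top_n = 20)
    save_csv(r, "rankings.csv")
    r
  })
  partners <- pipeline_stage("partners", {
    pc <- count_unique_partners(conn, target, cfg$weight_threshold)
    ct <- count_partner_celltypes(conn, target, cfg$weight_threshold)
    save_csv(data.frame(metric = c("partners", "celltypes"),
                        pre_only = c(pc$pre_only, ct$pre_only),
                        post_only = c(pc$post_only, ct$post_only),
                        both = c(pc$both, ct$both),
                        total = c(pc$total, ct$total)),
             "partner_counts.csv")
    list(partners = pc, celltypes = ct)
  })
  primacy <- pipeline_stage("primacy", {
    pt <- primacy_table(conn, target, cfg$strong_threshold)
    # reciprocity: aggregate weight from the target back to each cell type
    typ <- stats::setNames(conn$neurons$type,
                           as.character(conn$neurons$bodyId))
    eo <- conn$edges[conn$edges$bodyId_pre == target, , drop = FALSE]
    back <- tapply(eo$weight, unname(typ[as.character(eo$bodyId_post)]), sum)
    wf <- ifelse(pt$cell_type %in% names(back),
                 as.numeric(back[pt$cell_type]), 0)
    pt$weight_from_target <- wf
    pt$reciprocal <- mapply(classify_reciprocity, pt$weight_to_target, wf)
    save_csv(pt, "primacy.csv")
    pt
  })
  sub <- pipeline_stage("subconnectome", {
    s <- extract_input_subconnectome(conn, target)
    save_csv(s$neurons, "subconnectome_neurons.csv")
    s
  })
  clust <- pipeline_stage("cluster", {
    g <- to_undirected(sub)
    res <- reneel_maximize(g, chi = cfg$chi,
                           ensemble_size = cfg$ensemble_size,
                           seed = cfg$seed)
    write_partition(res$partition, out("partition.csv"))
    written <- c(written, "partition.csv")
    res$graph <- g
    res
  })
  comparison <- pipeline_stage("compare", {
    if (is.null(cfg$reference_partition)) NULL else {
      ref <- read_partition(cfg$reference_partition)
      jp <- joint_proportions(clust$partition, ref)
      sh <- shuffled_jaccard_baseline(clust$partition, ref,
                                      n_shuffles = cfg$n_shuffles,
                                      seed = cfg$seed)
      save_csv(as.data.frame(jp$counts), "joint_counts.csv", rn = TRUE)
      save_csv(data.frame(jaccard = sh$observed,
                          shuffled_mean = sh$mean, shuffled_sd = sh$sd),
               "comparison.csv")
      list(jaccard = sh$observed, joint = jp, shuffled = sh)
    }
  })
  consistency <- pipeline_stage("consistency", {
    if (cfg$n_runs < 2) NULL else {
      rc <- run_consistency(clust$graph, chi = cfg$chi, n_runs = cfg$n_runs,
                            master_seed = cfg$seed,
                            ensemble_size = cfg$ensemble_size)
      save_csv(data.frame(mean_jaccard = rc$mean_jaccard),
               "consistency.csv")
      rc
    }
  })
  similarity <- pipeline_stage("similarity", {
    M <- build_input_vectors(conn, sub$neurons$bodyId)
    ps <- shuffle_zscores(M, clust$partition, n_shuffles = cfg$n_shuffles,
                          seed = cfg$seed)
    save_csv(as.data.frame(ps$means), "similarity_means.csv", rn = TRUE)
    save_csv(as.data.frame(ps$z), "similarity_z.csv", rn = TRUE)
    ps
  })
  profiles <- pipeline_stage("neuropil", {
    tp <- target_input_profile(conn, target, clust$partition, roi_map)
    mp <- module_member_input_profile(conn, clust$partition, roi_map)
    save_csv(as.data.frame(tp), "target_input_profile.csv", rn = TRUE)
    save_csv(as.data.frame(mp), "module_input_profile.csv", rn = TRUE)
    list(target = tp, members = mp)
  })

  manifest <- list(
    created = "run",  # no timestamp: outputs must be byte-identical
    parameters = unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")],
    target_bodyId = target,
    n_neurons = nrow(conn$neurons),
    n_subconnectome = nrow(sub$neurons),
    clustering = list(score = clust$score, chi = cfg$chi,
                      n_modules = length(unique(unclass(clust$partition))),
                      iterations = clust$diagnostics$iterations,
                      master_seed = cfg$seed),
    input_digests = as.list(tools::md5sum(
      c(cfg$neuron_table, cfg$edge_table))),
    output_digests = as.list(tools::md5sum(
      file.path(cfg$out_dir, unique(written))))
  )
  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(connectome = conn, target = target, rankings = rank_tab,
                 partners = partners, primacy = primacy,
                 subconnectome = sub, clustering = clust,
                 comparison = comparison, consistency = consistency,
                 similarity = similarity, profiles = profiles,
                 manifest = manifest))
}
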