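# Maximization of generalized modularity density by Reduced Network Extremal
# Ensemble Learning (RenEEL): an ensemble of heuristic partitions is refined
# by collapsing the groups of nodes that every ensemble member co-assigns
# ("core groups") into single nodes, re-running the heuristic on the reduced
# graph, and replacing or shrinking the ensemble until one consensus
# partition remains.

# evaluate RNG-dependent code under a temporary seed, restoring global state
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  code
}

# ---- greedy local-move heuristic -------------------------------------------

# One level of seeded local moves on a gidx structure. Starts from
# singletons; repeatedly offers each node (in seeded random order) the move
# to a neighboring community (or to a fresh singleton) with the largest
# strictly positive Q_g gain. The gain is exact for every chi: moving a node
# changes only the terms of the donor and recipient communities, which are
# recomputed in closed form from their (m_C, K_C, n_C) running stats.
local_moves <- function(gi, chi, memb = seq_len(gi$n), eps = 1e-12) {
  n <- gi$n
  memb <- as.integer(memb)
  if (length(gi$w) == 0) return(memb)
  # adjacency lists in index form
  ends <- c(gi$ui, gi$vi)
  othr <- c(gi$vi, gi$ui)
  ww <- c(gi$w, gi$w)
  ord <- order(ends)
  adj_n <- split(othr[ord], ends[ord])
  adj_w <- split(ww[ord], ends[ord])
  adj_of <- function(i) as.character(i)

  m <- gi$m
  st <- gidx_comm_stats(gi, memb)
  mC <- st$mC
  KC <- st$KC
  nC <- st$nC
  free <- which(nC == 0)  # recycled empty community slots
  term <- function(mc, kc, nc) {
    rho <- if (nc > 1) 2 * mc / (nc * (nc - 1)) else 0
    (mc / m - (kc / (2 * m))^2) * rho^chi
  }

  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      key <- adj_of(i)
      nb <- adj_n[[key]]
      if (is.null(nb)) next
      a <- memb[i]
      wts <- adj_w[[key]]
      comms <- memb[nb]
      S <- rowsum(wts, comms)
      cand <- as.integer(rownames(S))
      Sv <- S[, 1]
      S_a <- if (a %in% cand) Sv[match(a, cand)] else 0
      # donor community with i removed
      mA2 <- mC[a] - S_a - gi$internal[i]
      KA2 <- KC[a] - gi$strength[i]
      nA2 <- nC[a] - gi$size[i]
      old_a <- term(mC[a], KC[a], nC[a])
      rem_a <- if (nA2 > 0) term(mA2, KA2, nA2) else 0
      gains <- numeric(0); targets <- integer(0); Sb <- numeric(0)
      for (k in seq_along(cand)) {
        b <- cand[k]
        if (b == a) next
        gain <- (rem_a - old_a) +
          term(mC[b] + Sv[k] + gi$internal[i], KC[b] + gi$strength[i],
               nC[b] + gi$size[i]) -
          term(mC[b], KC[b], nC[b])
        if (gain > eps) {
          gains <- c(gains, gain); targets <- c(targets, b); Sb <- c(Sb, Sv[k])
        }
      }
      if (nA2 > 0) {  # moving out into a fresh singleton community
        gain <- (rem_a - old_a) +
          term(gi$internal[i], gi$strength[i], gi$size[i])
        if (gain > eps) {
          if (length(free) == 0) {
            mC <- c(mC, 0); KC <- c(KC, 0); nC <- c(nC, 0)
            free <- length(mC)
          }
          gains <- c(gains, gain); targets <- c(targets, free[1])
          Sb <- c(Sb, 0)
        }
      }
      if (length(gains) == 0) next
      # randomized extremal greedy: a random strictly improving move,
      # gain-weighted; diversifies the local optima reached across seeds
      pick <- if (length(gains) == 1) 1 else
        sample.int(length(gains), 1, prob = gains)
      best_b <- targets[pick]; best_Sb <- Sb[pick]
      if (best_b != a) {
        mC[a] <- mA2; KC[a] <- KA2; nC[a] <- nA2
        mC[best_b] <- mC[best_b] + best_Sb + gi$internal[i]
        KC[best_b] <- KC[best_b] + gi$strength[i]
        nC[best_b] <- nC[best_b] + gi$size[i]
        memb[i] <- best_b
        free <- setdiff(free, best_b)
        if (nA2 == 0) free <- c(free, a)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# aggregate a ugraph by an integer membership over its nodes (gidx order);
# reduced node ids are 1..k in order of first appearance
aggregate_graph <- function(g, memb) {
  labs <- match(memb, unique(memb))
  k <- max(labs)
  ids <- g$nodes$id
  size <- as.numeric(rowsum(as.numeric(g$nodes$size), labs)[, 1])
  internal <- as.numeric(rowsum(as.numeric(g$nodes$internal), labs)[, 1])
  # rowsum sorts group keys; reorder back to 1..k
  ord <- sort(unique(labs))
  size[ord] <- size; internal[ord] <- internal
  e <- g$edges
  if (nrow(e) > 0) {
    cu <- labs[match(e$u, ids)]
    cv <- labs[match(e$v, ids)]
    within <- cu == cv
    if (any(within)) {
      s <- rowsum(e$weight[within], cu[within])
      internal[as.integer(rownames(s))] <-
        internal[as.integer(rownames(s))] + s[, 1]
    }
    eb <- data.frame(u = pmin(cu, cv)[!within], v = pmax(cu, cv)[!within],
                     weight = e$weight[!within])
  } else {
    eb <- data.frame(u = integer(0), v = integer(0), weight = numeric(0))
  }
  rg <- ugraph(eb, nodes = data.frame(id = seq_len(k), size = size,
                                      internal = internal))
  attr(rg, "members") <- split(as.character(ids), labs)
  rg
}

#' Greedy base heuristic for generalized modularity density
#'
#' Louvain-style seeded maximization of `Q_g`: repeated passes of single-node
#' local moves (each strictly increasing the score) followed by community
#' agglomeration, until neither improves. Used as the fast heuristic inside
#' [reneel_maximize()] and usable on annotated reduced graphs, where it
#' scores exactly as the expansion on the original graph.
#'
#' @param g a [ugraph()] with at least one edge or positive internal weight.
#' @param chi resolution exponent.
#' @param seed integer seed; results are deterministic for a fixed seed.
#' @return A [partition()] over `g`'s nodes with integer labels.
#' @export
base_heuristic <- function(g, chi = 0, seed = 1) {
  stopifnot(inherits(g, "ugraph"))
  gi <- gidx_build(g)
  if (gi$m <= 0) stop("graph has zero total weight", call. = FALSE)
  with_seed(seed, {
    climb <- function(chi_lvl, init) {
      # init: membership over original nodes (compressed 1..k) or NULL
      cur <- g
      assign_cur <- seq_len(gi$n)  # original node -> current-level node
      first_init <- if (is.null(init)) NULL else match(init, unique(init))
      best_memb <- if (is.null(first_init)) seq_len(gi$n) else first_init
      best_score <- gidx_score(gi, best_memb, chi_lvl)
      repeat {
        gic <- gidx_build(cur)
        start <- if (is.null(first_init)) seq_len(gic$n) else first_init
        first_init <- NULL
        lvl <- local_moves(gic, chi_lvl, start)
        lvl <- match(lvl, unique(lvl))
        cand <- lvl[assign_cur]
        sc <- gidx_score(gi, cand, chi_lvl)
        if (sc <= best_score + 1e-12 || max(lvl) == length(lvl)) {
          if (sc > best_score) { best_score <- sc; best_memb <- cand }
          break
        }
        best_score <- sc
        best_memb <- cand
        nxt <- aggregate_graph(cur, lvl)
        assign_cur <- lvl[assign_cur]
        cur <- nxt
      }
      list(memb = best_memb, score = best_score)
    }
    res <- climb(chi, NULL)
    # a climb from a random coarse start reaches local optima that the
    # singleton start cannot (groups that are only profitable once formed),
    # and diversifies the ensemble across seeds
    rand_init <- sample.int(max(2L, ceiling(gi$n / 2)), gi$n, replace = TRUE)
    res_r <- climb(chi, rand_init)
    if (res_r$score > res$score) res <- res_r
    if (chi > 0) {
      # At chi > 0 singleton communities contribute 0, so the greedy climb
      # from singletons can stall before small dense groups become
      # profitable; a second climb seeded from the coarse (chi = 0) solution
      # escapes that plateau. Keep whichever scores higher at the target chi.
      coarse <- climb(0, NULL)
      res2 <- climb(chi, coarse$memb)
      if (res2$score > res$score) res <- res2
    }
    partition(gi$ids, match(res$memb, unique(res$memb)))
  })
}

#' Core groups of a partition ensemble
#'
#' Two nodes belong to the same core group iff they are co-assigned in every
#' partition of the ensemble (the intersection of the co-membership
#' equivalence relations). Core groups refine every ensemble member.
#'
#' @param partitions non-empty list of [partition()]s over a common node set.
#' @return A [partition()] mapping each node to its core-group label.
#' @export
core_groups <- function(partitions) {
  if (length(partitions) == 0) stop("empty ensemble", call. = FALSE)
  ps <- lapply(partitions, as_partition)
  ids <- sort(names(ps[[1]]))
  for (p in ps) {
    if (!identical(sort(names(p)), ids)) {
      stop("ensemble partitions cover different node sets", call. = FALSE)
    }
  }
  key <- do.call(paste, c(lapply(ps, function(p) unclass(p)[ids]),
                          sep = "\r"))
  partition(ids, match(key, unique(key)))
}

#' Reduce a graph by a grouping of its nodes
#'
#' Collapses each group to a single node; inter-group edge weights are
#' summed, and every reduced node carries the group's total internal weight
#' and member count so any partition of the reduced graph scores exactly as
#' its expansion on the original graph.
#'
#' @param g a [ugraph()].
#' @param grouping a [partition()] covering `g`'s nodes.
#' @return A [ugraph()] with one node per group; attribute `members` maps
#'   each reduced node id to the original member ids.
#' @export
reduce_graph <- function(g, grouping) {
  stopifnot(inherits(g, "ugraph"))
  grouping <- as_partition(grouping)
  v <- unclass(grouping)[as.character(g$nodes$id)]
  if (anyNA(v)) stop("grouping does not cover every node", call. = FALSE)
  aggregate_graph(g, match(v, unique(v)))
}

# expand a partition of a reduced graph (with members attr) to original ids
expand_partition <- function(reduced_graph, p_reduced) {
  members <- attr(reduced_graph, "members")
  p_reduced <- as_partition(p_reduced)
  lab <- unclass(p_reduced)[as.character(seq_along(members))]
  ids <- unlist(members, use.names = FALSE)
  partition(ids, rep(lab, lengths(members)))
}

#' Maximize generalized modularity density with RenEEL
#'
#' Builds an ensemble of `ensemble_size` seeded [base_heuristic()] partitions
#' and iterates the reduce/replace scheme: collapse the ensemble's core
#' groups ([core_groups()]), run the heuristic on the reduced graph
#' ([reduce_graph()]), and expand the result. If the candidate duplicates an
#' ensemble member or scores strictly below every member, the ensemble
#' shrinks by one (dropping its worst member); otherwise the candidate
#' replaces the worst member. The loop ends when a single consensus
#' partition remains.
#'
#' @param g a [ugraph()].
#' @param chi resolution exponent (0 = coarse resolution).
#' @param ensemble_size initial ensemble size, `>= 2`. Default 20.
#' @param seed master seed; per-member and per-iteration seeds are derived
#'   from it and recorded in the diagnostics.
#' @param max_iter safety bound on reduce/replace iterations.
#' @return List with elements `partition` (the consensus [partition()]),
#'   `score` (its `Q_g` on the original graph), and `diagnostics`
#'   (iteration count, best-score trajectory, capacity trajectory, seeds).
#' @export
reneel_maximize <- function(g, chi = 0, ensemble_size = 20, seed = 1,
                            max_iter = 100 + 20 * ensemble_size) {
  stopifnot(inherits(g, "ugraph"))
  if (ensemble_size < 2) stop("ensemble_size must be >= 2", call. = FALSE)
  gi <- gidx_build(g)
  if (gi$m <= 0) stop("graph has zero total weight", call. = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                      ensemble_size + max_iter))
  ens <- vector("list", ensemble_size)
  for (j in seq_len(ensemble_size)) {
    p <- base_heuristic(g, chi, seeds[j])
    ens[[j]] <- list(p = p, key = canonical_key(p),
                     score = gidx_score(gi, partition_to_memb(gi, p), chi))
  }
  traj <- numeric(0)
  caps <- integer(0)
  iter <- 0
  while (length(ens) > 1 && iter < max_iter) {
    iter <- iter + 1
    cg <- core_groups(lapply(ens, `[[`, "p"))
    rg <- reduce_graph(g, cg)
    pr <- base_heuristic(rg, chi, seeds[ensemble_size + iter])
    cand <- expand_partition(rg, pr)
    key <- canonical_key(cand)
    sc <- gidx_score(gi, partition_to_memb(gi, cand), chi)
    scores <- vapply(ens, `[[`, numeric(1), "score")
    worst <- which.min(scores)
    if (key %in% vapply(ens, `[[`, character(1), "key") || sc < min(scores)) {
      ens[[worst]] <- NULL            # reduce: drop the worst member
    } else {
      ens[[worst]] <- list(p = cand, key = key, score = sc)  # replace
    }
    traj <- c(traj, max(vapply(ens, `[[`, numeric(1), "score")))
    caps <- c(caps, length(ens))
  }
  scores <- vapply(ens, `[[`, numeric(1), "score")
  best <- ens[[which.max(scores)]]
  list(partition = best$p, score = best$score,
       diagnostics = list(iterations = iter, best_score_trajectory = traj,
                          capacity_trajectory = caps, master_seed = seed,
                          converged = length(ens) == 1))
}

#' Exhaustive optimal partition (test oracle)
#'
#' Enumerates every set partition of the node set (restricted-growth-string
#' order) and returns the maximizer of `Q_g`. Feasible only for tiny graphs;
#' intended as an independent oracle for [reneel_maximize()].
#'
#' @param g a [ugraph()] with at most 10 nodes.
#' @param chi resolution exponent.
#' @return List with `partition` (first-encountered argmax, i.e. the
#'   lexicographically smallest canonical form among ties) and `score`.
#' @export
exhaustive_best_partition <- function(g, chi = 0) {
  stopifnot(inherits(g, "ugraph"))
  gi <- gidx_build(g)
  n <- gi$n
  if (n > 10) stop("exhaustive enumeration limited to 10 nodes", call. = FALSE)
  if (gi$m <= 0) stop("graph has zero total weight", call. = FALSE)
  a <- rep(1L, n)
  best_score <- -Inf
  best <- a
  repeat {
    sc <- gidx_score(gi, a, chi)
    if (sc > best_score + 1e-15) { best_score <- sc; best <- a }
    # next restricted growth string
    j <- n
    advanced <- FALSE
    while (j > 1) {
      if (a[j] <= max(a[seq_len(j - 1)])) {
        a[j] <- a[j] + 1L
        if (j < n) a[(j + 1):n] <- 1L
        advanced <- TRUE
        break
      }
      j <- j - 1
    }
    if (!advanced) break
  }
  list(partition = partition(gi$ids, best), score = best_score)
}
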