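# Graph partitioning with the two-sided stability score.
#
# A partition is an integer vector `mc` over the graph's nodes: 0 marks an
# outlier (excluded from scoring), 1..M are metacell indices.

new_partition <- function(mc) {
  mc <- as.integer(mc)
  structure(list(mc = mc, n_metacells = max(0L, max(mc))),
            class = "mc_partition")
}

compact_partition <- function(mc) {
  used <- sort(unique(mc[mc > 0L]))
  map <- integer(max(c(used, 1L)))
  map[used] <- seq_along(used)
  mc[mc > 0L] <- map[mc[mc > 0L]]
  new_partition(mc)
}

#' @export
print.mc_partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes, %d metacells, %d outliers\n",
              length(x$mc), x$n_metacells, sum(x$mc == 0L)))
  invisible(x)
}

#' Two-sided stability score of a partition
#'
#' For each assigned node `v`, `pstable_out` is the weighted fraction of its
#' outgoing edges that stay inside its metacell (and `pstable_in` the same
#' on incoming edges); `punif = |M_mc(v)| / |V|` is the retention a uniform
#' random walk would achieve. The score averages the log stability ratios
#' over both directions:
#' `score = 1/(2|V|) * sum_v [log(pstable_in/punif) + log(pstable_out/punif)]`.
#' `log(pstable)` is floored at `floor_log` so nodes with one-sided or
#' absent internal connectivity are strongly penalized rather than -Inf.
#' Outlier nodes and their edges are excluded from `V`.
#'
#' @param g a [build_balanced_knn()] graph.
#' @param partition an `mc_partition` (or an integer vector of metacell
#'   indices, 0 = outlier).
#' @param floor_log floor for `log(pstable)` (default -10).
#' @return list with `score` and `terms`, a per-node tibble of
#'   `pstable_in`, `pstable_out`, `punif`, `stable_in`, `stable_out`.
#' @export
compute_score <- function(g, partition, floor_log = -10) {
  mc <- if (inherits(partition, "mc_partition")) partition$mc
        else as.integer(partition)
  assert_that(length(mc) == g$n, "partition does not cover the graph")
  n <- g$n
  V <- sum(mc > 0L)
  assert_that(V > 0, "no assigned nodes to score")
  s <- Matrix::summary(methods::as(methods::as(g$w, "generalMatrix"),
                                   "CsparseMatrix"))
  keep <- mc[s$i] > 0L & mc[s$j] > 0L
  si <- s$i[keep]; sj <- s$j[keep]; sx <- s$x[keep]
  same <- mc[si] == mc[sj]
  tot_out <- tot_in <- same_out <- same_in <- numeric(n)
  tot_out[] <- 0; add <- rowsum(sx, si)
  tot_out[as.integer(rownames(add))] <- add
  add <- rowsum(sx, sj)
  tot_in[as.integer(rownames(add))] <- add
  if (any(same)) {
    add <- rowsum(sx[same], si[same])
    same_out[as.integer(rownames(add))] <- add
    add <- rowsum(sx[same], sj[same])
    same_in[as.integer(rownames(add))] <- add
  }
  idx <- which(mc > 0L)
  sizes <- tabulate(mc[idx])
  punif <- sizes[mc[idx]] / V
  flog <- function(num, den) {
    out <- rep(floor_log, length(num))
    ok <- den > 0 & num > 0
    out[ok] <- pmax(log(num[ok] / den[ok]), floor_log)
    out
  }
  lp_out <- flog(same_out[idx], tot_out[idx])
  lp_in <- flog(same_in[idx], tot_in[idx])
  terms <- tibble::tibble(
    node = idx,
    metacell = mc[idx],
    pstable_out = ifelse(tot_out[idx] > 0, same_out[idx] / tot_out[idx], 0),
    pstable_in = ifelse(tot_in[idx] > 0, same_in[idx] / tot_in[idx], 0),
    punif = punif,
    log_stable_out = lp_out - log(punif),
    log_stable_in = lp_in - log(punif))
  score <- sum(terms$log_stable_out + terms$log_stable_in) / (2 * V)
  list(score = score, terms = terms)
}

#' Seed an initial partition
#'
#' `P` seed nodes are drawn by exclusion sampling: iteratively sampling
#' nodes disconnected from the nodes selected so far and their neighbours;
#' when no such node remains, the remaining seeds are drawn uniformly from
#' unselected nodes. Every other node is then attached to the seed group
#' with the strongest connectivity (sum of balanced edge weights, ties to
#' the lower seed index), sweeping until full cover; nodes in components
#' holding no seed get a uniformly drawn group.
#'
#' @inheritParams compute_score
#' @param P number of seeds, from `ceil(sum(u') / U_targ)`.
#' @param seed RNG seed.
#' @return an `mc_partition` covering all nodes.
#' @export
seed_partition <- function(g, P, seed = 1L) {
  assert_that(P >= 1, "P must be >= 1")
  mc <- seed_within(g, seq_len(g$n), P, seed)
  new_partition(mc)
}

# seeding + propagation restricted to `nodes`; returns an assignment vector
# over all of g's nodes, 0 outside `nodes`, groups numbered 1..P' inside.
seed_within <- function(g, nodes, P, seed) {
  n <- g$n
  set.seed(seed)
  P <- max(1L, min(as.integer(P), length(nodes)))
  sym <- g$w + Matrix::t(g$w)
  in_set <- logical(n)
  in_set[nodes] <- TRUE
  eligible <- in_set & !g$isolated
  if (!any(eligible)) eligible <- in_set
  avail <- eligible
  seeds <- integer(0)
  while (length(seeds) < P && any(avail)) {
    w <- which(avail)
    s <- w[sample.int(length(w), 1L)]
    seeds <- c(seeds, s)
    nb <- which(sym[, s] != 0)
    avail[c(s, nb)] <- FALSE
  }
  if (length(seeds) < P) {
    pool <- setdiff(which(eligible), seeds)
    if (length(pool)) {
      extra <- pool[sample.int(length(pool), min(P - length(seeds),
                                                 length(pool)))]
      seeds <- c(seeds, extra)
    }
  }
  mc <- integer(n)
  mc[seeds] <- seq_along(seeds)
  repeat {
    un <- which(in_set & mc == 0L)
    if (!length(un)) break
    assigned <- which(in_set & mc > 0L)
    ind <- Matrix::sparseMatrix(i = assigned, j = mc[assigned], x = 1,
                                dims = c(n, length(seeds)))
    conn <- as.matrix(sym[un, , drop = FALSE] %*% ind)
    best <- max.col(conn, ties.method = "first")
    hit <- conn[cbind(seq_along(un), best)] > 0
    if (!any(hit)) {
      mc[un] <- sample.int(length(seeds), length(un), replace = TRUE)
      break
    }
    mc[un[hit]] <- best[hit]
  }
  mc
}

#' Optimize a partition by annealed hill climbing
#'
#' Single-node moves are swept in seeded random order. At annealing level
#' `lambda` a move of node `v` is accepted iff the change in the (summed)
#' score plus `lambda` times the change in `v`'s own stability terms is
#' positive; `lambda` starts high — letting nodes chase connectivity at
#' others' expense — and is reduced to 0, where the goal function itself is
#' optimized and the final score can only increase. Nodes outside `active`
#' move at `lambda = 0` regardless of the level.
#'
#' @inheritParams compute_score
#' @param p0 initial `mc_partition` (full cover of the non-outlier nodes).
#' @param lambda_schedule decreasing annealing weights, ending in 0.
#' @param seed RNG seed.
#' @param active logical vector: which nodes feel `lambda` (default all).
#' @param max_sweeps_pos sweep cap per positive-lambda level.
#' @return an `mc_partition` with `score(output) >= score(p0)` at
#'   `lambda = 0`.
#' @export
optimize_partition <- function(g, p0, lambda_schedule = c(4, 2, 1, 0.5, 0.25, 0),
                               seed = 1L, active = NULL,
                               max_sweeps_pos = 8L, floor_log = -10) {
  mc <- if (inherits(p0, "mc_partition")) p0$mc else as.integer(p0)
  if (is.null(active)) active <- rep(TRUE, g$n)
  w <- methods::as(methods::as(g$w, "generalMatrix"), "CsparseMatrix")
  tw <- methods::as(Matrix::t(w), "CsparseMatrix")
  res <- cpp_optimize_partition(
    g$n, tw@p, tw@i, tw@x, w@p, w@i, w@x,
    mc, active, as.numeric(lambda_schedule), as.integer(max_sweeps_pos),
    as.integer(seed), floor_log)
  compact_partition(res$assign)
}

# Dissolve the given metacells and redistribute their nodes: re-seed the
# dissolved nodes with `n_seeds` fresh groups (0 = attach to survivors by
# connectivity), then re-optimize with the lambda schedule active only on
# the dissolved nodes.
dissolve_and_reseed <- function(g, p, dissolve_ids, n_seeds, cfg, seed) {
  mc <- p$mc
  dn <- which(mc %in% dissolve_ids)
  mc[dn] <- 0L
  if (n_seeds >= 1) {
    sub <- seed_within(g, dn, n_seeds, derive_seed(seed, "reseed"))
    mc[dn] <- sub[dn] + max(mc)
  } else {
    mc[dn] <- attach_to_groups(g, mc, dn,
                               derive_seed(seed, "attach"))
  }
  active <- logical(g$n)
  active[dn] <- TRUE
  optimize_partition(g, new_partition(mc), cfg$lambda_schedule,
                     derive_seed(seed, "reopt"), active = active,
                     max_sweeps_pos = cfg$max_sweeps_pos,
                     floor_log = cfg$floor_log)
}

# attach `nodes` to existing groups in `mc` by strongest connectivity.
attach_to_groups <- function(g, mc, nodes, seed) {
  set.seed(seed)
  n <- g$n
  M <- max(mc)
  if (M == 0L) return(rep(1L, length(nodes)))
  sym <- g$w + Matrix::t(g$w)
  out <- integer(length(nodes))
  todo <- seq_along(nodes)
  repeat {
    assigned <- which(mc > 0L)
    ind <- Matrix::sparseMatrix(i = assigned, j = mc[assigned], x = 1,
                                dims = c(n, M))
    conn <- as.matrix(sym[nodes[todo], , drop = FALSE] %*% ind)
    best <- max.col(conn, ties.method = "first")
    hit <- conn[cbind(seq_along(todo), best)] > 0
    if (!any(hit)) {
      sz <- tabulate(mc[mc > 0L], M)
      out[todo] <- which.min(sz)
      break
    }
    out[todo[hit]] <- best[hit]
    mc[nodes[todo[hit]]] <- best[hit]
    todo <- todo[!hit]
    if (!length(todo)) break
  }
  out
}

metacell_u_totals <- function(mc, u_capped) {
  M <- max(mc)
  if (M == 0L) return(numeric(0))
  tot <- numeric(M)
  agg <- rowsum(u_capped[mc > 0L], mc[mc > 0L])
  tot[as.integer(rownames(agg))] <- agg
  tot
}

#' Dissolve metacells exceeding the maximal size
#'
#' Metacells whose capped UMI total reaches `U_high` are dissolved; their
#' nodes are re-seeded (exclusion sampling restricted to the dissolved
#' nodes, `ceil(sum u' / U_targ)` seeds) and the partition re-optimized
#' with the annealing schedule active only on the dissolved nodes.
#'
#' @inheritParams compute_score
#' @param p an `mc_partition`.
#' @param sizes a [cell_sizes()] for the pile's nodes.
#' @param cfg an [mc2_config()].
#' @param seed RNG seed.
#' @return list with `partition` and `dissolved` (how many metacells were).
#' @export
enforce_max_size <- function(g, p, sizes, cfg, seed = 1L) {
  tot <- metacell_u_totals(p$mc, sizes$u_capped)
  too_big <- which(tot >= sizes$U_high)
  if (!length(too_big)) return(list(partition = p, dissolved = 0L))
  nodes <- which(p$mc %in% too_big)
  n_seeds <- max(1L, ceiling(sum(sizes$u_capped[nodes]) / sizes$U_targ))
  p2 <- dissolve_and_reseed(g, p, too_big, n_seeds, cfg, seed)
  list(partition = p2, dissolved = length(too_big))
}

#' Split or dissolve weakly connected metacells
#'
#' Each metacell's induced subgraph (symmetrized weights) is tested with a
#' global min-cut: if the mean weight of cut pairs (absent pairs count as
#' weight 0) is below 10% of the mean weight of non-cut pairs, the metacell
#' is weakly connected. A smaller side of fewer than 7 cells is simply
#' disassociated (marked outlier); otherwise the whole metacell is
#' dissolved and its nodes re-seeded as in [enforce_max_size()].
#'
#' @inheritParams enforce_max_size
#' @param weak_ratio cut-vs-rest mean weight threshold (0.1).
#' @param min_split_cells sides smaller than this are disassociated (7).
#' @return list with `partition`, `n_dissolved`, `n_disassociated`.
#' @export
enforce_connectivity <- function(g, p, sizes, cfg, seed = 1L,
                                 weak_ratio = 0.1, min_split_cells = 7) {
  mc <- p$mc
  sym <- (g$w + Matrix::t(g$w)) / 2
  dissolve <- integer(0)
  outlier_nodes <- integer(0)
  for (m in seq_len(max(mc))) {
    nodes <- which(mc == m)
    nm <- length(nodes)
    if (nm < 2) next
    sub <- sym[nodes, nodes, drop = FALSE]
    cut <- weakest_cut(sub)
    if (is.null(cut)) next
    n1 <- length(cut$side1)
    n2 <- nm - n1
    mean_cut <- cut$value / (n1 * n2)
    pairs_within <- choose(n1, 2) + choose(n2, 2)
    if (pairs_within == 0) {
      weak <- mean_cut == 0
    } else {
      mean_rest <- (sum(sub) / 2 - cut$value) / pairs_within
      weak <- mean_cut < weak_ratio * mean_rest
    }
    if (!weak) next
    smaller <- if (n1 <= n2) cut$side1 else setdiff(seq_len(nm), cut$side1)
    if (length(smaller) < min_split_cells) {
      outlier_nodes <- c(outlier_nodes, nodes[smaller])
    } else {
      dissolve <- c(dissolve, m)
    }
  }
  if (!length(dissolve) && !length(outlier_nodes)) {
    return(list(partition = p, n_dissolved = 0L, n_disassociated = 0L))
  }
  mc[outlier_nodes] <- 0L
  p2 <- new_partition(mc)
  if (length(dissolve)) {
    nodes <- which(mc %in% dissolve)
    n_seeds <- max(1L, ceiling(sum(sizes$u_capped[nodes]) / sizes$U_targ))
    p2 <- dissolve_and_reseed(g, p2, dissolve, n_seeds, cfg, seed)
  } else {
    p2 <- compact_partition(p2$mc)
  }
  list(partition = p2, n_dissolved = length(dissolve),
       n_disassociated = length(outlier_nodes))
}

# global min cut of a symmetric weighted adjacency matrix; NULL when the
# matrix is smaller than 2 nodes. Returns indices (into the submatrix) of
# one side and the cut value.
weakest_cut <- function(sub) {
  nm <- nrow(sub)
  if (nm < 2) return(NULL)
  s <- Matrix::summary(methods::as(sub, "CsparseMatrix"))
  keep <- s$i < s$j & s$x > 0
  if (!any(keep)) {
    # fully disconnected: any single node forms a zero cut
    return(list(side1 = 1L, value = 0))
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = s$i[keep], to = s$j[keep], weight = s$x[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nm)))
  if (igraph::components(ig)$no > 1) {
    comp <- igraph::components(ig)$membership
    return(list(side1 = which(comp == 1), value = 0))
  }
  cut <- igraph::min_cut(ig, capacity = igraph::E(ig)$weight,
                         value.only = FALSE)
  list(side1 = as.integer(igraph::as_ids(cut$partition1)),
       value = cut$value)
}

#' Dissolve metacells below the minimal size
#'
#' A metacell is a *marker* metacell when at least one gene's
#' depth-normalized pooled expression is 8-fold above the mean over all
#' metacells. Metacells with capped UMI totals at or below `U_low` (no
#' marker) or `0.5 * U_low` (marker) are dissolved, as is any metacell with
#' fewer than 12 cells. Dissolved cells are re-seeded with one seed fewer
#' than the number of dissolved metacells and the partition re-optimized;
#' this iterates until all metacells meet the minimal size or the next
#' iteration would create a too-large metacell.
#'
#' @inheritParams enforce_max_size
#' @param counts the pile's cells x genes UMI matrix (for the marker test).
#' @param marker_fold marker fold threshold (8).
#' @param min_cells hard minimal metacell cell count (12).
#' @return list with `partition` and `converged`.
#' @export
enforce_min_size <- function(g, p, counts, sizes, cfg, seed = 1L,
                             marker_fold = 8, min_cells = 12) {
  for (iter in seq_len(cfg$max_iterations)) {
    mc <- p$mc
    M <- max(mc)
    if (M == 0L) return(list(partition = p, converged = TRUE))
    tot <- metacell_u_totals(mc, sizes$u_capped)
    ncells <- tabulate(mc[mc > 0L], M)
    marker <- marker_metacells(counts, mc, fold = marker_fold)
    low_bound <- ifelse(marker, 0.5 * sizes$U_low, sizes$U_low)
    dissolve <- which((tot <= low_bound | ncells < min_cells) & ncells > 0)
    if (!length(dissolve)) return(list(partition = p, converged = TRUE))
    if (length(dissolve) == M) {
      # nothing to rescue against: keep as-is, flagged unconverged
      return(list(partition = p, converged = FALSE))
    }
    n_seeds <- length(dissolve) - 1L
    p2 <- dissolve_and_reseed(g, p, dissolve, n_seeds, cfg,
                              derive_seed(seed, "minsize", iter))
    tot2 <- metacell_u_totals(p2$mc, sizes$u_capped)
    if (any(tot2 >= sizes$U_high)) {
      return(list(partition = p, converged = FALSE))
    }
    p <- p2
  }
  list(partition = p, converged = FALSE)
}

# depth-normalized pooled profiles; marker = any gene >= fold x the mean
# over metacells (regularized).
marker_metacells <- function(counts, mc, fold = 8, reg = 1e-5) {
  M <- max(mc)
  if (M == 0L) return(logical(0))
  assigned <- which(mc > 0L)
  ind <- Matrix::sparseMatrix(i = mc[assigned], j = assigned, x = 1,
                              dims = c(M, length(mc)))
  pooled <- ind %*% counts  # M x genes
  totals <- Matrix::rowSums(pooled)
  totals[totals == 0] <- 1
  frac <- as.matrix(pooled / totals)
  grand <- colMeans(frac)
  apply(frac, 1, function(f) any(f >= fold * (grand + reg)))
}

#' Partition one pile's graph into metacells
#'
#' The full per-pile loop: seeding, annealed optimization, then iterated
#' max-size and connectivity control until every metacell is below `U_high`
#' and passes the min-cut test, then min-size control. If the target size
#' implies fewer than 12 cells per metacell on average, `U_targ` is raised
#' to `12 * median(u)` first.
#'
#' @inheritParams enforce_min_size
#' @return list with `partition` (an `mc_partition`), `sizes` (possibly
#'   with a raised `U_targ`), and `warnings` (character).
#' @export
partition_pile <- function(g, counts, sizes, cfg, seed = 1L) {
  warnings <- character()
  if (sizes$U_targ / stats::median(sizes$u) < 12) {
    sizes <- cell_sizes(sizes$u, target_umis = 12 * stats::median(sizes$u))
  }
  P <- max(1L, ceiling(sum(sizes$u_capped) / sizes$U_targ))
  p <- seed_partition(g, P, derive_seed(seed, "seeding"))
  p <- optimize_partition(g, p, cfg$lambda_schedule,
                          derive_seed(seed, "optimize"),
                          max_sweeps_pos = cfg$max_sweeps_pos,
                          floor_log = cfg$floor_log)
  for (iter in seq_len(cfg$max_iterations)) {
    ms <- enforce_max_size(g, p, sizes, cfg, derive_seed(seed, "maxsize", iter))
    p <- ms$partition
    if (ms$dissolved > 0) next
    cc <- enforce_connectivity(g, p, sizes, cfg,
                               derive_seed(seed, "connect", iter))
    p <- cc$partition
    if (cc$n_dissolved == 0 && cc$n_disassociated == 0) break
    if (iter == cfg$max_iterations) {
      warnings <- c(warnings, "size/connectivity loop hit max_iterations")
    }
  }
  msz <- enforce_min_size(g, p, counts, sizes, cfg,
                          derive_seed(seed, "minsize"))
  if (!msz$converged) {
    warnings <- c(warnings, "min-size control stopped before convergence")
  }
  list(partition = msz$partition, sizes = sizes, warnings = warnings)
}

#' Export a partition as a cell-to-metacell TSV
#' @param partition an `mc_partition`.
#' @param cell_ids cell identifiers, same order as the partition nodes.
#' @param path output path; outliers are written as -1.
#' @export
write_partition_tsv <- function(partition, cell_ids, path) {
  write.table(
    data.frame(cell_id = cell_ids,
               metacell_id = ifelse(partition$mc == 0L, -1L,
                                    partition$mc - 1L)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
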