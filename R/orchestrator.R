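#' Configuration of the divide-and-conquer metacell algorithm
#'
#' @param target_umis target metacell size `U_targ` in UMIs (160000).
#' @param target_metacells_per_pile expected metacells per random pile
#'   (100; large atlases often use 50 for speed).
#' @param pile_min,pile_max hard bounds on random pile sizes in cells
#'   (10000, 30000).
#' @param forbidden_genes gene names never selected as features.
#' @param rare a [rare_detector_params()].
#' @param deviant a [deviant_params()].
#' @param lambda_schedule annealing weights for the optimizer, ending at 0.
#' @param max_sweeps_pos sweep cap per positive annealing level.
#' @param max_iterations cap for the size/connectivity and min-size loops.
#' @param floor_log floor for `log(pstable)` in the stability score.
#' @param downsample_min lower clip of the per-pile downsampling target.
#' @param metagroup_target_cells target metagroup size in member cells;
#'   6250 puts the hard ceiling (`2x`) at 12500 cells.
#' @param rare_enabled run the rare-gene-module pre-process?
#' @return an object of class `mc2_config`.
#' @export
mc2_config <- function(target_umis = 160000,
                       target_metacells_per_pile = 100,
                       pile_min = 10000, pile_max = 30000,
                       forbidden_genes = character(),
                       rare = rare_detector_params(),
                       deviant = deviant_params(),
                       lambda_schedule = c(4, 2, 1, 0.5, 0.25, 0),
                       max_sweeps_pos = 8L,
                       max_iterations = 20L,
                       floor_log = -10,
                       downsample_min = 500,
                       metagroup_target_cells = 6250,
                       rare_enabled = TRUE) {
  structure(as.list(environment()), class = "mc2_config")
}

#' Choose the random pile size
#'
#' The pile size targets `target_metacells_per_pile` expected metacells:
#' `target_metacells_per_pile * U_targ / median(u)`, clamped to
#' `[pile_min, pile_max]` cells. Datasets no larger than one pile are
#' processed directly.
#'
#' @param n_cells number of cells in the dataset.
#' @param target_umis target metacell size in UMIs.
#' @param median_cell_umis median per-cell total UMIs.
#' @inheritParams mc2_config
#' @return integer pile size in cells.
#' @export
choose_pile_size <- function(n_cells, target_umis, median_cell_umis,
                             target_metacells_per_pile = 100,
                             pile_min = 10000, pile_max = 30000) {
  raw <- target_metacells_per_pile * target_umis / median_cell_umis
  as.integer(round(clamp(raw, pile_min, pile_max)))
}

# seeded shuffle, near-equal contiguous blocks; pile count chosen so pile
# sizes respect [pile_min, pile_max] whenever n allows it.
make_random_piles <- function(n, pile_size, seed,
                              pile_min = 10000, pile_max = 30000) {
  if (n <= pile_size) {
    return(list(seq_len(n)))
  }
  npiles <- min(round(n / pile_size), floor(n / pile_min))
  npiles <- max(npiles, ceiling(n / pile_max), 1L)
  set.seed(seed)
  perm <- sample.int(n)
  base <- n %/% npiles
  extra <- n %% npiles
  sizes <- rep(base, npiles) + c(rep(1L, extra), rep(0L, npiles - extra))
  split(perm, rep.int(seq_len(npiles), sizes))
}

# The basic per-pile algorithm: downsample, select features, build the
# balanced K-nn graph, partition with the two-sided stability score, then
# either remove deviant cells or (force_coverage) re-attach any outliers.
# `u_override` switches the size-accounting unit (used by the metagroup
# phase, where an observation is a pooled metacell and its "UMIs" are its
# member-cell count); `target_override` replaces U_targ in that unit.
compute_pile_metacells <- function(m_pile, cfg, seed, force_coverage = FALSE,
                                   u_override = NULL,
                                   target_override = NULL) {
  n <- nrow(m_pile)
  umis <- Matrix::rowSums(m_pile)
  u <- u_override %||% umis
  target <- target_override %||% cfg$target_umis
  if (n < 2) {
    return(list(partition = new_partition(rep(if (force_coverage) 1L else 0L,
                                              n)),
                warnings = "degenerate pile (fewer than 2 cells)"))
  }
  sizes <- cell_sizes(u, target)
  ds_target <- as.integer(clamp(round(quantile(umis, 0.05, names = FALSE)),
                                cfg$downsample_min, cfg$target_umis))
  ds <- downsample_cells(m_pile, ds_target, derive_seed(seed, "downsample"))
  fs <- tryCatch(select_features(ds, cfg$forbidden_genes),
                 error = function(e) NULL)
  if (is.null(fs)) {
    mcv <- rep(if (force_coverage) 1L else 0L, n)
    return(list(partition = new_partition(mcv),
                warnings = "pile unpartitionable: no feature genes"))
  }
  K <- choose_K(sizes$u, sizes$U_targ)
  g <- build_balanced_knn(ds[, fs$feature_genes, drop = FALSE], K)
  pp <- partition_pile(g, ds, sizes, cfg, seed)
  part <- pp$partition
  warnings <- pp$warnings
  if (force_coverage) {
    out_nodes <- which(part$mc == 0L)
    if (length(out_nodes)) {
      mcv <- part$mc
      if (max(mcv) == 0L) {
        mcv[] <- 1L
      } else {
        mcv[out_nodes] <- attach_to_groups(g, mcv, out_nodes,
                                           derive_seed(seed, "cover"))
      }
      part <- compact_partition(mcv)
    }
  } else {
    dr <- iterate_deviant_removal(ds, part, cfg$deviant, pp$sizes)
    part <- dr$partition
  }
  list(partition = part, warnings = warnings, K = K,
       feature_genes = fs$feature_genes, graph = g, downsampled = ds)
}

#' Preliminary phase: random piles to a full (low-quality) cover
#'
#' Cells are split into seeded random piles; each pile runs the basic
#' algorithm with deviant removal. Outliers from all piles are pooled and
#' re-piled repeatedly until they fit a single pile, which is partitioned
#' forcing 100% coverage (no deviant removal; residual outliers re-attached
#' by connectivity). Every cell ends up in some preliminary metacell.
#'
#' @param m cells x genes UMI matrix.
#' @param cfg an [mc2_config()].
#' @param seed master seed.
#' @param pile_size from [choose_pile_size()].
#' @return list with `mc` (integer per cell, dense 1..M, no zeros) and
#'   `n_pile_runs`.
#' @export
preliminary_phase <- function(m, cfg, seed = 1L, pile_size = NULL) {
  n <- nrow(m)
  pile_size <- pile_size %||% choose_pile_size(
    n, cfg$target_umis, stats::median(Matrix::rowSums(m)),
    cfg$target_metacells_per_pile, cfg$pile_min, cfg$pile_max)
  mc <- integer(n)
  next_id <- 0L
  todo <- seq_len(n)
  level <- 0L
  n_runs <- 0L
  repeat {
    level <- level + 1L
    piles <- make_random_piles(length(todo), pile_size,
                               derive_seed(seed, "prelim_piles", level),
                               cfg$pile_min, cfg$pile_max)
    single <- length(piles) == 1L
    force <- single && level > 1L
    outliers <- integer(0)
    for (k in seq_along(piles)) {
      cells <- todo[piles[[k]]]
      res <- compute_pile_metacells(
        m[cells, , drop = FALSE], cfg,
        derive_seed(seed, "prelim", level * 10000L + k),
        force_coverage = force)
      n_runs <- n_runs + 1L
      pm <- res$partition$mc
      assigned <- pm > 0L
      mc[cells[assigned]] <- pm[assigned] + next_id
      next_id <- next_id + max(0L, max(pm))
      outliers <- c(outliers, cells[!assigned])
      rm(res)
      gc(verbose = FALSE)
    }
    if (!length(outliers)) break
    if (single && level > 1L) break  # forced coverage leaves none anyway
    if (level >= 20L) break          # pathological non-shrinking pool
    if (single) {
      # a one-pile dataset: its outliers form the final outlier pile
      todo <- outliers
      next
    }
    todo <- outliers
  }
  # safety: force-cover any cell that slipped through (e.g. degenerate pile)
  if (any(mc == 0L)) {
    mc[mc == 0L] <- next_id + 1L
  }
  list(mc = compact_partition(mc)$mc, n_pile_runs = n_runs,
       pile_size = pile_size)
}

#' Metagroup phase: group preliminary metacells
#'
#' Each preliminary metacell becomes one observation (its pooled UMI
#' counts); the divide-and-conquer grouping is invoked on these
#' observations with 100% coverage, with sizes accounted in member cells
#' (target `metagroup_target_cells`, hard ceiling twice that) instead of
#' UMIs. Recursion only triggers when there are more observations than one
#' pile.
#'
#' @param prelim_mc integer per cell: preliminary metacell ids (1..M).
#' @inheritParams preliminary_phase
#' @return integer per preliminary metacell: metagroup id (1..G).
#' @export
metagroup_phase <- function(prelim_mc, m, cfg, seed = 1L, pile_size = NULL) {
  M <- max(prelim_mc)
  ind <- Matrix::sparseMatrix(i = prelim_mc, j = seq_along(prelim_mc), x = 1,
                              dims = c(M, length(prelim_mc)))
  pooled <- methods::as(ind %*% m, "CsparseMatrix")
  rownames(pooled) <- sprintf("prelim_mc_%05d", seq_len(M))
  colnames(pooled) <- colnames(m)
  u_obs <- as.numeric(tabulate(prelim_mc, M))
  pile_size <- pile_size %||% cfg$pile_min
  group_observations(pooled, u_obs, cfg, seed, pile_size, depth = 1L)
}

# recursive forced-coverage grouping of observation profiles with sizes in
# `u_obs` units.
group_observations <- function(pooled, u_obs, cfg, seed, pile_size, depth) {
  M <- nrow(pooled)
  if (M <= pile_size) {
    res <- compute_pile_metacells(
      pooled, cfg, derive_seed(seed, "metagroup", depth),
      force_coverage = TRUE, u_override = u_obs,
      target_override = cfg$metagroup_target_cells)
    return(res$partition$mc)
  }
  piles <- make_random_piles(M, pile_size,
                             derive_seed(seed, "mg_piles", depth),
                             cfg$pile_min, cfg$pile_max)
  mc <- integer(M)
  next_id <- 0L
  for (k in seq_along(piles)) {
    obs <- piles[[k]]
    res <- compute_pile_metacells(
      pooled[obs, , drop = FALSE], cfg,
      derive_seed(seed, "metagroup", depth * 10000L + k),
      force_coverage = TRUE, u_override = u_obs[obs],
      target_override = cfg$metagroup_target_cells)
    mc[obs] <- res$partition$mc + next_id
    next_id <- next_id + max(res$partition$mc)
  }
  # recurse on the groups' pooled profiles
  G <- max(mc)
  ind <- Matrix::sparseMatrix(i = mc, j = seq_len(M), x = 1,
                              dims = c(G, M))
  pooled2 <- methods::as(ind %*% pooled, "CsparseMatrix")
  rownames(pooled2) <- sprintf("group_%05d", seq_len(G))
  colnames(pooled2) <- colnames(pooled)
  u2 <- as.numeric(ind %*% u_obs)
  upper <- group_observations(pooled2, u2, cfg, seed + 1L, pile_size,
                              depth + 1L)
  upper[mc]
}

#' Final phase: high-quality metacells within metagroups
#'
#' Each metagroup's cells form one pile processed by the basic algorithm
#' with deviant removal; outliers from all piles are pooled, re-piled and
#' re-partitioned exactly once (again with deviant removal), and the
#' outliers of that second level become final outliers.
#'
#' @param metagroup_of_cell integer per cell: metagroup id.
#' @inheritParams preliminary_phase
#' @return list with `mc` (integer per cell, 0 = final outlier),
#'   `pile_of_metacell`, `piles` (list of cell index vectors), and
#'   `warnings`.
#' @export
final_phase <- function(metagroup_of_cell, m, cfg, seed = 1L,
                        pile_size = NULL) {
  n <- nrow(m)
  pile_size <- pile_size %||% choose_pile_size(
    n, cfg$target_umis, stats::median(Matrix::rowSums(m)),
    cfg$target_metacells_per_pile, cfg$pile_min, cfg$pile_max)
  mc <- integer(n)
  next_id <- 0L
  pile_of_metacell <- integer(0)
  piles <- split(seq_len(n), metagroup_of_cell)
  all_warnings <- character()
  pile_registry <- list()
  pile_seeds <- integer(0)
  outliers <- integer(0)
  for (k in seq_along(piles)) {
    cells <- piles[[k]]
    pile_seed <- derive_seed(seed, "final", k)
    res <- compute_pile_metacells(m[cells, , drop = FALSE], cfg, pile_seed)
    pm <- res$partition$mc
    n_new <- max(0L, max(pm))
    mc[cells[pm > 0L]] <- pm[pm > 0L] + next_id
    pile_id <- length(pile_registry) + 1L
    pile_registry[[pile_id]] <- cells
    pile_seeds <- c(pile_seeds, pile_seed)
    pile_of_metacell <- c(pile_of_metacell, rep(pile_id, n_new))
    next_id <- next_id + n_new
    outliers <- c(outliers, cells[pm == 0L])
    all_warnings <- c(all_warnings, res$warnings)
    rm(res)
    gc(verbose = FALSE)
  }
  if (length(outliers)) {
    opiles <- make_random_piles(length(outliers), pile_size,
                                derive_seed(seed, "final_outlier_piles"),
                                cfg$pile_min, cfg$pile_max)
    for (k in seq_along(opiles)) {
      cells <- outliers[opiles[[k]]]
      if (length(cells) < 2) next
      pile_seed <- derive_seed(seed, "final_outlier", k)
      res <- compute_pile_metacells(m[cells, , drop = FALSE], cfg, pile_seed)
      pm <- res$partition$mc
      n_new <- max(0L, max(pm))
      mc[cells[pm > 0L]] <- pm[pm > 0L] + next_id
      pile_id <- length(pile_registry) + 1L
      pile_registry[[pile_id]] <- cells
      pile_seeds <- c(pile_seeds, pile_seed)
      pile_of_metacell <- c(pile_of_metacell, rep(pile_id, n_new))
      next_id <- next_id + n_new
      all_warnings <- c(all_warnings, res$warnings)
    }
  }
  cp <- compact_partition(mc)
  keep <- sort(unique(mc[mc > 0L]))
  list(mc = cp$mc, pile_of_metacell = pile_of_metacell[keep],
       piles = pile_registry, pile_seeds = pile_seeds,
       warnings = all_warnings)
}

#' Run the basic algorithm directly (single pile plus one outlier pass)
#'
#' The whole dataset is processed as one pile with deviant removal; the
#' resulting outliers are re-partitioned exactly once, and cells still
#' unassigned after that pass are final outliers. This is the path
#' [run_mc2()] takes when the dataset fits a single pile.
#'
#' @inheritParams preliminary_phase
#' @return a `metacell_solution`.
#' @export
run_direct <- function(m, cfg = mc2_config(), seed = 1L) {
  validate_umi_matrix(m)
  fp <- final_phase(rep(1L, nrow(m)), m, cfg, seed,
                    pile_size = nrow(m))
  build_solution(m, fp$mc, provenance = rep("main", max(fp$mc)),
                 pile_of_metacell = fp$pile_of_metacell,
                 piles = fp$piles, pile_seeds = fp$pile_seeds,
                 cfg = cfg, seed = seed, warnings = fp$warnings)
}

#' Derive a metacell cover of a UMI matrix
#'
#' The full algorithm: the rare-gene-module pre-process first derives
#' metacells for cells expressing rare modules (each module's cells form a
#' dedicated pile); the remaining cells run through the three
#' divide-and-conquer phases (preliminary random piles, metagroups, final
#' piles). Datasets fitting one pile skip the divide-and-conquer and run
#' the direct basic algorithm. Metacell ids are merged densely; every input
#' cell ends in exactly one metacell or as a final outlier.
#'
#' @inheritParams preliminary_phase
#' @return an object of class `metacell_solution`; see [tidy()] /
#'   [glance()] methods, `$assignment` (integer per cell, 0 = final
#'   outlier), `$profiles` (metacells x genes pooled counts), and
#'   `$provenance` (per metacell: "main" or "rare_module_<k>").
#' @export
run_mc2 <- function(m, cfg = mc2_config(), seed = 1L) {
  validate_umi_matrix(m)
  n <- nrow(m)
  pile_size <- choose_pile_size(
    n, cfg$target_umis, stats::median(Matrix::rowSums(m)),
    cfg$target_metacells_per_pile, cfg$pile_min, cfg$pile_max)
  mc <- integer(n)
  provenance <- character(0)
  pile_of_metacell <- integer(0)
  piles <- list()
  pile_seeds <- integer(0)
  warnings <- character()
  next_id <- 0L
  main_cells <- seq_len(n)
  if (cfg$rare_enabled) {
    det <- detect_rare_modules(m, cfg$rare, pile_size)
    for (k in seq_along(det$modules)) {
      cells <- match(det$modules[[k]]$cells_CM, rownames(m))
      pile_seed <- derive_seed(seed, "rare", k)
      # a rare pile may hold as few as 12 cells, far below U_targ in UMIs;
      # cap the pile's size target at its own (capped) UMI total so the
      # module can form a valid metacell instead of dissolving
      u_pile <- Matrix::rowSums(m[cells, , drop = FALSE])
      rare_target <- min(cfg$target_umis,
                         sum(pmin(u_pile, 2 * stats::median(u_pile))))
      res <- compute_pile_metacells(m[cells, , drop = FALSE], cfg, pile_seed,
                                    target_override = rare_target)
      pm <- res$partition$mc
      n_new <- max(0L, max(pm))
      mc[cells[pm > 0L]] <- pm[pm > 0L] + next_id
      if (n_new > 0) {
        pile_id <- length(piles) + 1L
        piles[[pile_id]] <- cells
        pile_seeds <- c(pile_seeds, pile_seed)
        pile_of_metacell <- c(pile_of_metacell, rep(pile_id, n_new))
        provenance <- c(provenance, rep(sprintf("rare_module_%d", k), n_new))
        next_id <- next_id + n_new
      }
      warnings <- c(warnings, res$warnings)
    }
    main_cells <- which(mc == 0L)  # rare-pile outliers rejoin the main run
  }
  if (length(main_cells)) {
    msub <- m[main_cells, , drop = FALSE]
    if (length(main_cells) <= pile_size) {
      sol_main <- run_direct(msub, cfg, seed)
      main_mc <- sol_main$assignment
      main_piles <- lapply(sol_main$piles, function(p) main_cells[p])
      main_pile_of_mc <- sol_main$pile_of_metacell
      main_pile_seeds <- sol_main$pile_seeds
      n_main <- sol_main$n_metacells
      warnings <- c(warnings, sol_main$warnings)
    } else {
      prelim <- preliminary_phase(msub, cfg, seed, pile_size)
      groups <- metagroup_phase(prelim$mc, msub, cfg, seed,
                                pile_size = pile_size)
      fp <- final_phase(groups[prelim$mc], msub, cfg, seed, pile_size)
      main_mc <- fp$mc
      main_piles <- lapply(fp$piles, function(p) main_cells[p])
      main_pile_of_mc <- fp$pile_of_metacell
      main_pile_seeds <- fp$pile_seeds
      n_main <- max(0L, max(main_mc))
      warnings <- c(warnings, fp$warnings)
    }
    assigned <- main_mc > 0L
    mc[main_cells[assigned]] <- main_mc[assigned] + next_id
    pile_offset <- length(piles)
    piles <- c(piles, main_piles)
    pile_seeds <- c(pile_seeds, main_pile_seeds)
    pile_of_metacell <- c(pile_of_metacell, main_pile_of_mc + pile_offset)
    provenance <- c(provenance, rep("main", n_main))
    next_id <- next_id + n_main
  }
  build_solution(m, mc, provenance = provenance,
                 pile_of_metacell = pile_of_metacell, piles = piles,
                 pile_seeds = pile_seeds, cfg = cfg, seed = seed,
                 warnings = warnings)
}
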