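#' Inner normalized variance of one metacell
#'
#' Member cells are downsampled to a common total (the minimum member
#' total, floored at 100 UMIs); for genes with at least 40 UMIs in total
#' the normalized variance (variance over mean) across the downsampled
#' cells is computed, and the 95th percentile over those genes is the inner
#' normalized variance. Under the ideal model — members sampled from one
#' multinomial — the statistic concentrates near 1.
#'
#' @param m cells x genes UMI matrix of the metacell's member cells.
#' @param seed RNG seed for the downsampling.
#' @param min_gene_umis qualifying-gene threshold (40 total UMIs).
#' @param prob percentile (0.95).
#' @param min_target lower bound of the downsampling target (100).
#' @return a single number, or `NA` when fewer than 2 cells or no gene
#'   qualifies.
#' @export
inner_normalized_variance <- function(m, seed = 1L, min_gene_umis = 40,
                                      prob = 0.95, min_target = 100) {
  if (nrow(m) < 2) return(NA_real_)
  target <- max(min_target, min(Matrix::rowSums(m)))
  ds <- downsample_cells(m, target, seed)
  tot <- Matrix::colSums(ds)
  ok <- tot >= min_gene_umis
  if (!any(ok)) return(NA_real_)
  mu <- tot[ok] / nrow(ds)
  v <- col_var_sparse(ds[, ok, drop = FALSE])
  as.numeric(quantile(v / mu, prob, names = FALSE))
}

#' Inner normalized variance for every metacell of a solution
#'
#' @param solution a `metacell_solution`.
#' @param m the original cells x genes UMI matrix.
#' @param seed RNG seed.
#' @return tibble with `metacell`, `n_cells`, `inner_normalized_variance`.
#' @export
solution_inv <- function(solution, m, seed = 1L) {
  rows <- lapply(seq_len(solution$n_metacells), function(k) {
    cells <- which(solution$assignment == k)
    tibble::tibble(
      metacell = k,
      n_cells = length(cells),
      inner_normalized_variance = inner_normalized_variance(
        m[cells, , drop = FALSE], seed = derive_seed(seed, "inv", k)))
  })
  do.call(rbind, rows)
}

#' Match metacell size distributions across solutions
#'
#' Comparing inner-variance distributions across solutions is biased by
#' their metacell sizes. Working separately within each annotated cell
#' type, metacells are sorted by size in every solution and rank-matched;
#' each matched metacell is subsampled to the minimal cell count at its
#' rank across solutions. Works for any number of solutions
#' simultaneously; types absent from some solution are skipped with a
#' warning, as are unmatched ranks.
#'
#' @param solutions list of `metacell_solution`s.
#' @param types list (same length) of per-cell type labels.
#' @param seed RNG seed for the subsampling.
#' @return tibble with `solution`, `type`, `rank`, `metacell`,
#'   `original_cells`, `adjusted_cells`, and `cells`, a list column of the
#'   kept cell indices.
#' @export
match_size_distributions <- function(solutions, types, seed = 1L) {
  assert_that(length(solutions) >= 2 && length(types) == length(solutions),
              "need >= 2 solutions with matching type label vectors")
  all_types <- sort(unique(unlist(types)))
  set.seed(seed)
  out <- list()
  for (ty in all_types) {
    per_sol <- lapply(seq_along(solutions), function(s) {
      sol <- solutions[[s]]
      cells_ty <- which(types[[s]] == ty & sol$assignment > 0L)
      mcs <- unique(sol$assignment[cells_ty])
      sizes <- vapply(mcs, function(k) sum(sol$assignment[cells_ty] == k),
                      integer(1))
      ord <- order(sizes, decreasing = TRUE)
      list(mcs = mcs[ord], sizes = sizes[ord], cells_ty = cells_ty)
    })
    counts <- vapply(per_sol, function(p) length(p$mcs), integer(1))
    if (any(counts == 0)) {
      warning(sprintf("type '%s' absent from some solution; skipped", ty))
      next
    }
    n_rank <- min(counts)
    if (any(counts > n_rank)) {
      warning(sprintf("type '%s': unmatched metacells beyond rank %d left unadjusted",
                      ty, n_rank))
    }
    for (r in seq_len(n_rank)) {
      target <- min(vapply(per_sol, function(p) p$sizes[r], integer(1)))
      for (s in seq_along(solutions)) {
        p <- per_sol[[s]]
        k <- p$mcs[r]
        cells <- p$cells_ty[solutions[[s]]$assignment[p$cells_ty] == k]
        kept <- if (length(cells) > target)
          sort(cells[sample.int(length(cells), target)]) else cells
        out[[length(out) + 1L]] <- tibble::tibble(
          solution = s, type = ty, rank = r, metacell = k,
          original_cells = length(cells), adjusted_cells = length(kept),
          cells = list(kept))
      }
    }
  }
  do.call(rbind, out)
}

#' Screen for rare marker genes across metacells
#'
#' Flags genes expressed in their top metacell at least `fold`-fold higher
#' than in `quantile` of all other metacells (expression compared on
#' depth-normalized pooled profiles).
#'
#' @param solution a `metacell_solution`.
#' @param fold fold threshold (8).
#' @param quantile reference quantile over the other metacells (0.998).
#' @return tibble with `gene`, `top_metacell`, `top_expression`,
#'   `reference_expression`, `fold`.
#' @export
screen_rare_marker_genes <- function(solution, fold = 8, quantile = 0.998) {
  M <- solution$n_metacells
  if (M < 2) {
    return(tibble::tibble(gene = character(), top_metacell = integer(),
                          top_expression = numeric(),
                          reference_expression = numeric(), fold = numeric()))
  }
  prof <- solution$profiles
  tot <- Matrix::rowSums(prof)
  tot[tot == 0] <- 1
  frac <- as.matrix(prof / tot)
  rows <- list()
  for (gi in seq_len(ncol(frac))) {
    f <- frac[, gi]
    top <- unname(which.max(f))
    if (f[top] <= 0) next
    ref <- stats::quantile(f[-top], quantile, names = FALSE)
    if (f[top] >= fold * ref) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = colnames(frac)[gi], top_metacell = top,
        top_expression = f[top], reference_expression = ref,
        fold = if (ref > 0) f[top] / ref else Inf)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(gene = character(), top_metacell = integer(),
                          top_expression = numeric(),
                          reference_expression = numeric(), fold = numeric()))
  }
  do.call(rbind, rows)
}

#' Per-gene AUROC for a rare module's cells
#'
#' Positives are the cells of metacells derived from the module's cell set;
#' each gene's per-cell expression fraction is scored as a classifier for
#' them via the rank-sum AUROC. Fold enrichment is the regularized ratio of
#' the positive and background mean fractions.
#'
#' @param solution a `metacell_solution`.
#' @param module a `rare_gene_module` (or list with `cells_CM`).
#' @param m the cells x genes UMI matrix.
#' @param reg regularization for the fold ratio.
#' @return tibble with `gene`, `auroc`, `fold_enrichment`, sorted by
#'   descending AUROC.
#' @export
rare_behavior_auroc <- function(solution, module, m, reg = 1e-5) {
  pos_mcs <- unique(solution$assignment[match(module$cells_CM,
                                              solution$cell_ids)])
  pos_mcs <- pos_mcs[!is.na(pos_mcs) & pos_mcs > 0L]
  positive <- solution$assignment %in% pos_mcs
  assert_that(any(positive), "no positive cells for this module")
  tot <- Matrix::rowSums(m)
  tot[tot == 0] <- 1
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  out <- lapply(seq_len(ncol(m)), function(gi) {
    f <- as.numeric(m[, gi]) / tot
    r <- rank(f)
    auroc <- (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    tibble::tibble(gene = colnames(m)[gi], auroc = auroc,
                   fold_enrichment = (mean(f[positive]) + reg) /
                     (mean(f[!positive]) + reg))
  })
  res <- do.call(rbind, out)
  res[order(-res$auroc), ]
}

#' Module score distribution over a cell partitioning
#'
#' Each cell is scored by the fraction of its UMIs coming from the module's
#' genes. The group (metacell or cluster) with the highest mean score
#' defines a threshold at half its median score; every cell at or above the
#' threshold, anywhere, is a positive.
#'
#' @param partitioning integer per cell: group ids (0 allowed for
#'   unassigned).
#' @param module a `rare_gene_module` (or list with `expanded_genes`).
#' @param m the cells x genes UMI matrix.
#' @return list with `scores` (per cell), `top_group`, `threshold`,
#'   `positives` (cell indices).
#' @export
rare_score_distribution <- function(partitioning, module, m) {
  genes <- intersect(module$expanded_genes %||% module$genes, colnames(m))
  tot <- Matrix::rowSums(m)
  tot[tot == 0] <- 1
  score <- if (length(genes)) {
    as.numeric(Matrix::rowSums(m[, genes, drop = FALSE])) / tot
  } else {
    numeric(nrow(m))
  }
  groups <- sort(unique(partitioning[partitioning > 0L]))
  if (!length(groups) || all(score == 0)) {
    return(list(scores = score, top_group = NA_integer_, threshold = NA_real_,
                positives = integer()))
  }
  means <- vapply(groups, function(g) mean(score[partitioning == g]),
                  numeric(1))
  top <- groups[which.max(means)]
  threshold <- 0.5 * stats::median(score[partitioning == top])
  positives <- if (threshold > 0) which(score >= threshold) else
    which(score > 0 & score >= threshold)
  list(scores = score, top_group = top, threshold = threshold,
       positives = positives)
}

#' Verify the min-cut connectivity of a solution's metacells
#'
#' Rebuilds each final pile's balanced K-nn graph exactly as it was built
#' during derivation (same derived downsampling seed, fresh feature
#' selection) and applies the weak-cut test to every metacell's induced
#' subgraph: a metacell fails when a global min cut exists whose mean
#' cut-pair weight is below `weak_ratio` times the mean non-cut-pair
#' weight.
#'
#' @param solution a `metacell_solution` carrying its pile registry.
#' @param m the original cells x genes UMI matrix.
#' @param weak_ratio the weak-cut threshold (0.1).
#' @return tibble with `metacell`, `pile`, `n_cells`, `connected`.
#' @export
check_metacell_connectivity <- function(solution, m, weak_ratio = 0.1) {
  cfg <- solution$config
  rows <- list()
  for (pid in seq_along(solution$piles)) {
    cells <- solution$piles[[pid]]
    mcs <- which(solution$pile_of_metacell == pid)
    if (!length(mcs)) next
    sub <- m[cells, , drop = FALSE]
    umis <- Matrix::rowSums(sub)
    ds_target <- as.integer(clamp(round(quantile(umis, 0.05, names = FALSE)),
                                  cfg$downsample_min, cfg$target_umis))
    ds <- downsample_cells(sub, ds_target,
                           derive_seed(solution$pile_seeds[pid], "downsample"))
    fs <- tryCatch(select_features(ds, cfg$forbidden_genes),
                   error = function(e) NULL)
    if (is.null(fs)) next
    K <- choose_K(umis, cfg$target_umis)
    g <- build_balanced_knn(ds[, fs$feature_genes, drop = FALSE], K)
    sym <- (g$w + Matrix::t(g$w)) / 2
    for (k in mcs) {
      nodes <- which(solution$assignment[cells] == k)
      connected <- TRUE
      if (length(nodes) >= 2) {
        cut <- weakest_cut(sym[nodes, nodes, drop = FALSE])
        if (!is.null(cut)) {
          n1 <- length(cut$side1)
          n2 <- length(nodes) - n1
          mean_cut <- cut$value / (n1 * n2)
          pairs_within <- choose(n1, 2) + choose(n2, 2)
          if (pairs_within > 0) {
            mean_rest <- (sum(sym[nodes, nodes]) / 2 - cut$value) /
              pairs_within
            connected <- !(mean_cut < weak_ratio * mean_rest)
          } else {
            connected <- mean_cut > 0
          }
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metacell = k, pile = pid, n_cells = length(nodes),
        connected = connected)
    }
  }
  do.call(rbind, rows)
}

#' QC report of a solution
#'
#' @param solution a `metacell_solution`.
#' @param m the original UMI matrix.
#' @param seed RNG seed.
#' @return tibble: per-metacell inner normalized variance plus sizes.
#' @export
qc_report <- function(solution, m, seed = 1L) {
  inv <- solution_inv(solution, m, seed)
  inv$total_umis <- Matrix::rowSums(solution$profiles)
  inv$provenance <- solution$provenance
  inv
}

#' Plot the inner-normalized-variance distribution of a QC report
#' @param report a [qc_report()] tibble.
#' @return a ggplot.
#' @export
plot_inv_distribution <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = inner_normalized_variance)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "inner normalized variance (95th pct of var/mean)",
                  y = "metacells")
}
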