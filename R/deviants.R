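#' Parameters of adaptive deviant (outlier) cell detection
#'
#' A gene is deviant when some cell over-expresses it at least
#' `T_fold`-fold relative to its metacell's pooled expectation; the
#' baseline `T_fold = 8` is doubled until at most `max_deviant_gene_fraction`
#' of the genes are deviant. Each cell is scored by the minimal rank of its
#' fold factors over the deviant genes (rank 1 = most extreme per gene);
#' cells with score at most `T_N` are deviant. `T_N` starts at 1 and is
#' doubled to the largest value that keeps at most
#' `max_deviant_cell_fraction` of the cells deviant — which also guarantees
#' no single gene removes more than `T_N` cells.
#'
#' @param T_fold_baseline baseline linear fold threshold (8).
#' @param max_deviant_gene_fraction cap on the deviant-gene fraction (0.03).
#' @param T_N_baseline baseline per-gene removal budget (1).
#' @param max_deviant_cell_fraction cap on the deviant-cell fraction (0.25).
#' @return an object of class `deviant_params`.
#' @export
deviant_params <- function(T_fold_baseline = 8,
                           max_deviant_gene_fraction = 0.03,
                           T_N_baseline = 1,
                           max_deviant_cell_fraction = 0.25) {
  assert_that(T_fold_baseline > 1, "T_fold baseline must exceed 1")
  assert_that(max_deviant_gene_fraction > 0 && max_deviant_gene_fraction < 1 &&
                max_deviant_cell_fraction > 0 && max_deviant_cell_fraction < 1,
              "fractions must be in (0, 1)")
  structure(list(T_fold_baseline = T_fold_baseline,
                 max_deviant_gene_fraction = max_deviant_gene_fraction,
                 T_N_baseline = T_N_baseline,
                 max_deviant_cell_fraction = max_deviant_cell_fraction),
            class = "deviant_params")
}

#' Fold factors of cells against their metacell's pooled profile
#'
#' For every nonzero count, `fold(c, g) = (x_cg + 1) / (expected_cg + 1)`
#' where `expected_cg` is the metacell's pooled gene fraction scaled to the
#' cell's total UMIs. The +1 regularization keeps sparse counts comparable;
#' zero counts have fold at most 1 and are not materialized. Cells of
#' singleton metacells and outlier cells get fold 1.
#'
#' @param m downsampled cells x genes UMI matrix of one pile.
#' @param partition an `mc_partition` over the pile's cells.
#' @return an object of class `fold_factors`: sparse cells x genes matrix
#'   of folds on the count support, plus the partition used.
#' @export
compute_fold_factors <- function(m, partition) {
  mc <- partition$mc
  assert_that(length(mc) == nrow(m), "partition does not match the matrix")
  M <- max(mc)
  cell_tot <- Matrix::rowSums(m)
  if (M > 0L) {
    assigned <- which(mc > 0L)
    ind <- Matrix::sparseMatrix(i = mc[assigned], j = assigned, x = 1,
                                dims = c(M, nrow(m)))
    pooled <- as.matrix(Matrix::t(ind %*% m))  # genes x M
    tot <- colSums(pooled)
    tot[tot == 0] <- 1
    profile <- sweep(pooled, 2, tot, "/")
  } else {
    profile <- matrix(0, ncol(m), 0)
  }
  mt <- methods::as(Matrix::t(m), "CsparseMatrix")  # genes x cells CSC
  folds_x <- cpp_fold_factors(mt@p, mt@i, mt@x, cell_tot, mc, profile,
                              tabulate(mc[mc > 0L], max(M, 1L)))
  ff <- mt
  ff@x <- folds_x
  structure(list(folds = Matrix::t(ff), partition = partition),
            class = "fold_factors")
}

#' Detect deviant cells with adaptive thresholds
#'
#' @param ff a [compute_fold_factors()] result.
#' @param params a [deviant_params()].
#' @return list with `deviant_cells` (integer indices), `T_fold`, `T_N`,
#'   `deviant_genes` (integer indices), and `report`, a tibble of
#'   (cell, gene, fold, rank) for the flagged cells.
#' @export
detect_deviants <- function(ff, params = deviant_params()) {
  folds <- methods::as(ff$folds, "CsparseMatrix")  # cells x genes
  mc <- ff$partition$mc
  n_cells <- nrow(folds)
  n_genes <- ncol(folds)
  gene_max <- col_max_sparse(folds)
  T_fold <- params$T_fold_baseline
  repeat {
    frac_genes <- mean(gene_max >= T_fold)
    if (frac_genes <= params$max_deviant_gene_fraction) break
    T_fold <- T_fold * 2
  }
  dev_genes <- which(gene_max >= T_fold)
  empty <- list(deviant_cells = integer(), T_fold = T_fold,
                T_N = params$T_N_baseline, deviant_genes = dev_genes,
                report = tibble::tibble(cell = integer(), gene = integer(),
                                        fold = numeric(), rank = integer()))
  if (!length(dev_genes)) return(empty)
  # per deviant gene, rank assigned cells by descending fold (ties by cell
  # index); cell score = min rank over deviant genes
  score <- rep(Inf, n_cells)
  best <- vector("list", length(dev_genes))
  s <- Matrix::summary(folds[, dev_genes, drop = FALSE])
  s <- s[mc[s$i] > 0L & s$x >= T_fold, , drop = FALSE]
  if (!nrow(s)) return(empty)
  for (k in seq_along(dev_genes)) {
    rows <- s[s$j == k, , drop = FALSE]
    if (!nrow(rows)) next
    ord <- order(-rows$x, rows$i)
    rnk <- seq_along(ord)
    cells <- rows$i[ord]
    upd <- rnk < score[cells]
    score[cells[upd]] <- rnk[upd]
    best[[k]] <- tibble::tibble(cell = cells, gene = dev_genes[k],
                                fold = rows$x[ord], rank = rnk)
  }
  caps <- params$T_N_baseline
  while (TRUE) {
    nxt <- caps[length(caps)] * 2
    caps <- c(caps, nxt)
    if (nxt > n_cells) break
  }
  max_dev <- params$max_deviant_cell_fraction * sum(mc > 0L)
  T_N <- params$T_N_baseline
  for (cand in caps) {
    if (sum(score <= cand) <= max_dev) T_N <- cand else break
  }
  deviant <- which(score <= T_N)
  if (length(deviant) > max_dev) {
    # even the baseline exceeds the cap: keep the most extreme by score
    deviant <- deviant[order(score[deviant])][seq_len(floor(max_dev))]
  }
  rep_tab <- do.call(rbind, best)
  rep_tab <- rep_tab[rep_tab$cell %in% deviant & rep_tab$rank <= T_N, ,
                     drop = FALSE]
  list(deviant_cells = deviant, T_fold = T_fold, T_N = T_N,
       deviant_genes = dev_genes, report = rep_tab)
}

#' Iterated deviant removal and small-metacell dissolution
#'
#' Alternates fold-factor computation (against freshly pooled profiles) and
#' deviant detection, marking deviants as outliers, until no new deviants
#' appear or the cumulative 25% cap is reached; then dissolves metacells
#' violating the minimal size (fewer than 12 cells, or capped UMI totals at
#' or below `U_low` — half that for marker metacells), marking their cells
#' as outliers too.
#'
#' @param m downsampled cells x genes pile matrix.
#' @param partition the pile's `mc_partition`.
#' @param params a [deviant_params()].
#' @param sizes a [cell_sizes()] for the pile.
#' @param marker_fold,min_cells min-size rule constants (8, 12).
#' @return list with `partition` (outliers marked), `n_deviant`,
#'   `n_dissolved_cells`, `iterations`, and a combined `report`.
#' @export
iterate_deviant_removal <- function(m, partition, params = deviant_params(),
                                    sizes = NULL, marker_fold = 8,
                                    min_cells = 12) {
  if (is.null(sizes)) sizes <- cell_sizes(m)
  mc <- partition$mc
  n0 <- sum(mc > 0L)
  cap <- floor(params$max_deviant_cell_fraction * n0)
  removed <- 0L
  reports <- list()
  iter <- 0L
  while (removed < cap) {
    iter <- iter + 1L
    p <- new_partition(mc)
    ff <- compute_fold_factors(m, p)
    det <- detect_deviants(ff, params)
    new_dev <- det$deviant_cells
    if (!length(new_dev)) break
    if (removed + length(new_dev) > cap) {
      new_dev <- new_dev[seq_len(cap - removed)]
    }
    mc[new_dev] <- 0L
    removed <- removed + length(new_dev)
    if (nrow(det$report)) {
      rep_i <- det$report
      rep_i$iteration <- iter
      reports[[iter]] <- rep_i
    }
  }
  # dissolve too-small metacells; their cells become outliers
  M <- max(mc)
  dissolved_cells <- 0L
  if (M > 0L) {
    tot <- metacell_u_totals(mc, sizes$u_capped)
    ncells <- tabulate(mc[mc > 0L], M)
    marker <- marker_metacells(m, mc, fold = marker_fold)
    low_bound <- ifelse(marker, 0.5 * sizes$U_low, sizes$U_low)
    bad <- which((ncells < min_cells | tot <= low_bound) & ncells > 0)
    if (length(bad)) {
      cells <- which(mc %in% bad)
      dissolved_cells <- length(cells)
      mc[cells] <- 0L
    }
  }
  report <- if (length(reports)) do.call(rbind, reports) else
    tibble::tibble(cell = integer(), gene = integer(), fold = numeric(),
                   rank = integer(), iteration = integer())
  list(partition = compact_partition(mc), n_deviant = removed,
       n_dissolved_cells = dissolved_cells, iterations = iter,
       report = report)
}
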