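#' Parameters of the rare-gene-module detector
#'
#' A rare gene is observed in at most `max_cell_fraction` of all cells yet
#' reaches at least `min_max_umis` UMIs in at least one cell. Candidate
#' modules are maximal Ward subtrees of the second-order correlation matrix
#' with at least `min_module_genes` genes and mean r2 of at least
#' `min_mean_r2`. Module expansion admits genes whose UMI frequency among
#' the module's cells is `expansion_fold` times their global frequency, as
#' long as the expressing-cell set grows less than
#' `expansion_cell_growth_cap`-fold. A cell belongs to a module's cell set
#' `C^M` when it has at least `min_module_umis_per_cell` UMIs from the
#' expanded module. Modules with fewer than 12 such cells, or more than
#' enough to put `pile_target_cells` of them in an average random pile, are
#' discarded.
#'
#' @param max_cell_fraction maximal expressing-cell fraction (default 1e-3).
#' @param min_max_umis minimal per-cell maximum UMI count (default 7).
#' @param min_module_genes minimal genes per candidate module (default 4).
#' @param min_mean_r2 minimal mean within-subtree r2 (default 0.1).
#' @param expansion_fold frequency enrichment required of added genes
#'   (default 128).
#' @param expansion_cell_growth_cap maximal expressing-cell growth factor
#'   during expansion (default 4).
#' @param min_module_umis_per_cell UMIs needed for C^M membership
#'   (default 4).
#' @param pile_target_cells expected per-pile occupancy defining the
#'   too-common bound T (default 48).
#' @return an object of class `rare_detector_params`.
#' @export
rare_detector_params <- function(max_cell_fraction = 1e-3,
                                 min_max_umis = 7,
                                 min_module_genes = 4,
                                 min_mean_r2 = 0.1,
                                 expansion_fold = 128,
                                 expansion_cell_growth_cap = 4,
                                 min_module_umis_per_cell = 4,
                                 pile_target_cells = 48) {
  p <- as.list(environment())
  assert_that(all(unlist(p) > 0) && max_cell_fraction < 1,
              "rare detector parameters must be positive, fraction < 1")
  structure(p, class = "rare_detector_params")
}

#' Identify rare genes
#'
#' @param m a cells x genes UMI matrix.
#' @param params a [rare_detector_params()].
#' @return character vector of rare gene names (possibly empty).
#' @export
find_rare_genes <- function(m, params = rare_detector_params()) {
  validate_umi_matrix(m)
  frac <- col_n_at_least(m, 1) / nrow(m)
  mx <- col_max_sparse(m)
  colnames(m)[frac <= params$max_cell_fraction & frac > 0 &
                mx >= params$min_max_umis]
}

#' Second-order gene-gene correlation
#'
#' `r` is the Pearson correlation between genes, computed on
#' `log2(count + 1)` over the cells expressing at least one of the rare
#' genes; `r2 = cor(r)` correlates the correlation patterns themselves,
#' which sharpens weak but consistent co-expression. Zero-variance rows
#' yield correlation 0 rather than NA.
#'
#' @param expr a rare-genes x cells (or cells x rare-genes) count matrix.
#' @return a symmetric matrix `r2` with unit diagonal, genes in both
#'   dimensions.
#' @export
second_order_correlation <- function(expr) {
  x <- as.matrix(expr)
  assert_that(nrow(x) >= 2, "need at least two rare genes")
  lx <- log2(x + 1)
  r <- safe_cor(t(lx))        # genes as variables
  r2 <- safe_cor(r)           # correlation of correlation rows
  dimnames(r2) <- list(rownames(expr), rownames(expr))
  r2
}

#' Candidate modules from Ward clustering of r2
#'
#' Genes are clustered with Ward's method on `1 - r2` distances; every
#' maximal subtree with at least `min_module_genes` leaves and mean
#' off-diagonal r2 of at least `min_mean_r2` is returned. Maximality is
#' top-down: a qualifying subtree swallows any qualifying subtree below it.
#'
#' @param r2 a symmetric correlation matrix with gene names.
#' @inheritParams find_rare_genes
#' @return list of character vectors (seed gene sets), possibly empty.
#' @export
candidate_modules <- function(r2, params = rare_detector_params()) {
  assert_that(is.matrix(r2) && nrow(r2) == ncol(r2), "r2 must be square")
  n <- nrow(r2)
  if (n < params$min_module_genes) return(list())
  hc <- stats::hclust(stats::as.dist(1 - r2), method = "ward.D2")
  # leaves under each merge node
  leaves <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaves[[k]] <- c(
      if (kids[1] < 0) -kids[1] else leaves[[kids[1]]],
      if (kids[2] < 0) -kids[2] else leaves[[kids[2]]])
  }
  qualifies <- function(idx) {
    length(idx) >= params$min_module_genes &&
      mean_offdiag(r2[idx, idx, drop = FALSE]) >= params$min_mean_r2
  }
  out <- list()
  # walk top-down from the root; stop descending at a qualifying subtree
  walk <- function(node) {
    if (node < 0) return(invisible())
    idx <- leaves[[node]]
    if (qualifies(idx)) {
      out[[length(out) + 1L]] <<- rownames(r2)[sort(idx)]
      return(invisible())
    }
    walk(hc$merge[node, 1])
    walk(hc$merge[node, 2])
  }
  walk(nrow(hc$merge))
  out
}

mean_offdiag <- function(x) {
  n <- nrow(x)
  if (n < 2) return(NA_real_)
  (sum(x) - sum(diag(x))) / (n * (n - 1))
}

#' Expand a candidate module and collect its cells
#'
#' `C` is the set of cells with any UMI of the seed genes. Genes whose UMI
#' frequency (gene UMIs over total UMIs) within `C` is at least
#' `expansion_fold` times their global frequency are added greedily in
#' descending enrichment order, each addition re-tested against the
#' expressing-cell growth cap. `C^M` is the set of cells with at least
#' `min_module_umis_per_cell` UMIs from the expanded module. Modules with
#' `|C^M| < 12` are discarded as too few; modules with `|C^M| > T` as too
#' common, where `T = pile_target_cells * n_cells / pile_size`.
#'
#' @param module character vector of seed gene names.
#' @param m a cells x genes UMI matrix.
#' @inheritParams find_rare_genes
#' @param pile_size the random pile size the detector is protecting against.
#' @return an object of class `rare_gene_module`: list with `seed_genes`,
#'   `expanded_genes`, `cells_CM`, `discarded`, `reason`.
#' @export
expand_module <- function(module, m, params = rare_detector_params(),
                          pile_size = 10000) {
  assert_that(length(module) >= 1, "empty module")
  T_max <- params$pile_target_cells * nrow(m) / pile_size
  in_C <- Matrix::rowSums(m[, module, drop = FALSE]) >= 1
  C <- which(in_C)
  expanded <- module
  if (length(C)) {
    tot_C <- sum(m[C, , drop = FALSE])
    tot_all <- sum(m)
    freq_C <- Matrix::colSums(m[C, , drop = FALSE]) / tot_C
    freq_all <- Matrix::colSums(m) / tot_all
    enrich <- ifelse(freq_all > 0, freq_C / freq_all, 0)
    cand <- setdiff(colnames(m)[enrich >= params$expansion_fold], module)
    cand <- cand[order(enrich[cand], decreasing = TRUE)]
    n_expr <- sum(Matrix::rowSums(m[, expanded, drop = FALSE]) >= 1)
    cap <- params$expansion_cell_growth_cap * length(C)
    for (g in cand) {
      n_new <- sum(Matrix::rowSums(m[, c(expanded, g), drop = FALSE]) >= 1)
      if (n_new < cap) {
        expanded <- c(expanded, g)
        n_expr <- n_new
      }
    }
  }
  module_umis <- Matrix::rowSums(m[, expanded, drop = FALSE])
  cells_CM <- rownames(m)[module_umis >= params$min_module_umis_per_cell]
  reason <- NULL
  if (length(cells_CM) < 12) {
    reason <- "too_few"
  } else if (length(cells_CM) > T_max) {
    reason <- "too_common"
  }
  structure(
    list(seed_genes = module, expanded_genes = expanded, cells_CM = cells_CM,
         discarded = !is.null(reason), reason = reason %||% NA_character_,
         T_max = T_max),
    class = "rare_gene_module")
}

#' Detect rare gene modules
#'
#' Composes [find_rare_genes()], [second_order_correlation()],
#' [candidate_modules()] and [expand_module()]. Cells claimed by several
#' modules are given to the module for which they carry the largest
#' module-UMI total (ties to the lower module index).
#'
#' @inheritParams expand_module
#' @return a list with `modules` (non-discarded `rare_gene_module`s, with
#'   disjoint `cells_CM`), `cells` (the union of their cell ids), and
#'   `report` (a tibble over all candidates, including discarded ones).
#' @export
detect_rare_modules <- function(m, params = rare_detector_params(),
                                pile_size = 10000) {
  empty <- list(modules = list(), cells = character(),
                report = tibble::tibble(module = integer(),
                                        n_seed_genes = integer(),
                                        n_expanded_genes = integer(),
                                        n_cells = integer(),
                                        status = character()))
  rare <- find_rare_genes(m, params)
  if (length(rare) < params$min_module_genes) return(empty)
  in_any <- Matrix::rowSums(m[, rare, drop = FALSE]) >= 1
  expr <- Matrix::t(m[in_any, rare, drop = FALSE])  # genes x expressing cells
  if (ncol(expr) < 2) return(empty)
  r2 <- second_order_correlation(expr)
  cands <- candidate_modules(r2, params)
  if (!length(cands)) return(empty)
  mods <- lapply(cands, expand_module, m = m, params = params,
                 pile_size = pile_size)
  kept <- Filter(function(x) !x$discarded, mods)
  # overlap resolution: each cell goes to its strongest module
  if (length(kept) > 1) {
    cell_pool <- unique(unlist(lapply(kept, `[[`, "cells_CM")))
    umis <- vapply(kept, function(mod) {
      as.numeric(Matrix::rowSums(m[cell_pool, mod$expanded_genes,
                                   drop = FALSE]))
    }, numeric(length(cell_pool)))
    winner <- max.col(umis, ties.method = "first")
    for (k in seq_along(kept)) {
      kept[[k]]$cells_CM <- intersect(kept[[k]]$cells_CM,
                                      cell_pool[winner == k])
    }
    kept <- Filter(function(x) length(x$cells_CM) >= 12, kept)
  }
  report <- do.call(rbind, lapply(seq_along(mods), function(k) {
    tibble::tibble(module = k,
                   n_seed_genes = length(mods[[k]]$seed_genes),
                   n_expanded_genes = length(mods[[k]]$expanded_genes),
                   n_cells = length(mods[[k]]$cells_CM),
                   status = if (mods[[k]]$discarded) mods[[k]]$reason
                            else "kept")
  }))
  list(modules = kept, cells = unlist(lapply(kept, `[[`, "cells_CM")),
       report = report)
}

#' Write a rare-module report as TSV
#' @param detection result of [detect_rare_modules()].
#' @param path output TSV path.
#' @export
write_rare_module_report <- function(detection, path) {
  tab <- do.call(rbind, lapply(seq_along(detection$modules), function(k) {
    mod <- detection$modules[[k]]
    data.frame(module_id = k,
               seed_genes = paste(mod$seed_genes, collapse = ","),
               expanded_genes = paste(mod$expanded_genes, collapse = ","),
               n_cells = length(mod$cells_CM),
               status = "kept")
  }))
  if (is.null(tab)) {
    tab <- data.frame(module_id = integer(), seed_genes = character(),
                      expanded_genes = character(), n_cells = integer(),
                      status = character())
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
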