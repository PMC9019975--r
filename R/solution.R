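# The final product: a metacell cover of the input cells.

build_solution <- function(m, mc, provenance, pile_of_metacell, piles,
                           cfg, seed, pile_seeds = integer(0),
                           warnings = character()) {
  mc <- as.integer(mc)
  M <- max(0L, max(mc))
  if (M > 0L) {
    assigned <- which(mc > 0L)
    ind <- Matrix::sparseMatrix(i = mc[assigned], j = assigned, x = 1,
                                dims = c(M, nrow(m)))
    profiles <- methods::as(ind %*% m, "CsparseMatrix")
    rownames(profiles) <- sprintf("mc_%05d", seq_len(M))
    colnames(profiles) <- colnames(m)
  } else {
    profiles <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                     x = numeric(), dims = c(0L, ncol(m)))
  }
  structure(
    list(assignment = mc,
         cell_ids = rownames(m),
         n_cells = nrow(m),
         n_metacells = M,
         n_outliers = sum(mc == 0L),
         profiles = profiles,
         provenance = provenance,
         pile_of_metacell = pile_of_metacell,
         piles = piles,
         pile_seeds = pile_seeds,
         metacell_n_cells = tabulate(mc[mc > 0L], M),
         config = cfg,
         seed = seed,
         warnings = warnings,
         qc = list()),
    class = "metacell_solution")
}

#' @export
print.metacell_solution <- function(x, ...) {
  cat(sprintf("metacell solution: %d cells -> %d metacells, %d final outliers (%.2f%%)\n",
              x$n_cells, x$n_metacells, x$n_outliers,
              100 * x$n_outliers / x$n_cells))
  if (x$n_metacells > 0) {
    cat(sprintf("  cells per metacell: median %d [%d, %d]; %d rare-module metacells\n",
                as.integer(stats::median(x$metacell_n_cells)),
                min(x$metacell_n_cells), max(x$metacell_n_cells),
                sum(startsWith(x$provenance, "rare"))))
  }
  invisible(x)
}

#' Tidy a metacell solution into a per-cell tibble
#'
#' @param x a `metacell_solution`.
#' @param ... unused.
#' @return tibble with `cell_id`, `metacell` (NA for final outliers),
#'   `outlier`, `provenance`.
#' @export
tidy.metacell_solution <- function(x, ...) {
  mcna <- ifelse(x$assignment == 0L, NA_integer_, x$assignment)
  tibble::tibble(
    cell_id = x$cell_ids,
    metacell = mcna,
    outlier = x$assignment == 0L,
    provenance = ifelse(is.na(mcna), NA_character_, x$provenance[mcna]))
}

#' One-row summary of a metacell solution
#'
#' @inheritParams tidy.metacell_solution
#' @export
glance.metacell_solution <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_metacells = x$n_metacells,
    n_outliers = x$n_outliers,
    outlier_fraction = x$n_outliers / x$n_cells,
    n_rare_metacells = sum(startsWith(x$provenance, "rare")),
    median_cells_per_metacell = if (x$n_metacells)
      stats::median(x$metacell_n_cells) else NA_real_,
    seed = x$seed)
}

#' Plot the metacell size distribution of a solution
#'
#' @param object a `metacell_solution`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metacell_solution <- function(object, ...) {
  df <- tibble::tibble(cells = object$metacell_n_cells,
                       provenance = object$provenance)
  ggplot2::ggplot(df, ggplot2::aes(x = cells, fill = provenance)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "cells per metacell", y = "metacells",
                  title = "metacell size distribution")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a metacell solution to disk
#'
#' Writes the cell-to-metacell map as TSV (`-1` for final outliers), the
#' pooled metacell UMI matrix as an MTX directory and (when requested) an
#' AnnData-layout HDF5 container, and a JSON run manifest.
#'
#' @param solution a `metacell_solution`.
#' @param dir output directory (created).
#' @param h5 also write the pooled matrix as `.h5ad`?
#' @return `dir`, invisibly.
#' @export
export_solution <- function(solution, dir, h5 = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(
    data.frame(cell_id = solution$cell_ids,
               metacell_id = solution$assignment - 1L),
    file.path(dir, "cell_metacell.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (solution$n_metacells > 0) {
    save_umi_matrix(solution$profiles, file.path(dir, "metacell_umis"))
    if (h5) save_umi_matrix(solution$profiles,
                            file.path(dir, "metacell_umis.h5ad"),
                            format = "h5")
  }
  manifest <- list(
    n_cells = solution$n_cells,
    n_metacells = solution$n_metacells,
    n_outliers = solution$n_outliers,
    seed = solution$seed,
    provenance = as.list(table(solution$provenance)),
    target_umis = solution$config$target_umis,
    warnings = solution$warnings)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
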