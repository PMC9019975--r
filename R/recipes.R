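#' Dataset cleaning recipes
#'
#' A filter recipe removes unwanted genes and low-quality cells before
#' metacell derivation. Removed genes are the union of all-zero genes, an
#' explicit exclusion list, and (optionally) mitochondrial genes recognized
#' by the case-insensitive name prefix `MT-`. Removed cells are those whose
#' total UMIs fall outside `[min_cell_umis, max_cell_umis]` or whose
#' fraction of UMIs coming from the removed genes exceeds
#' `max_excluded_fraction`; that fraction is computed against the cell's
#' total over all genes, before gene removal.
#'
#' @param excluded_gene_names character vector of gene names to drop.
#' @param exclude_mitochondrial drop genes whose name starts with `MT-`
#'   (case-insensitive)?
#' @param min_cell_umis,max_cell_umis inclusive per-cell UMI bounds.
#' @param max_excluded_fraction maximal tolerated fraction of a cell's UMIs
#'   coming from excluded genes, in `[0, 1]`.
#' @return an object of class `filter_recipe`.
#' @export
filter_recipe <- function(excluded_gene_names = character(),
                          exclude_mitochondrial = TRUE,
                          min_cell_umis = 0,
                          max_cell_umis = Inf,
                          max_excluded_fraction = 1) {
  assert_that(min_cell_umis <= max_cell_umis,
              "min_cell_umis must be <= max_cell_umis")
  assert_that(max_excluded_fraction >= 0 && max_excluded_fraction <= 1,
              "max_excluded_fraction must be in [0, 1]")
  structure(
    list(excluded_gene_names = as.character(excluded_gene_names),
         exclude_mitochondrial = isTRUE(exclude_mitochondrial),
         min_cell_umis = min_cell_umis,
         max_cell_umis = max_cell_umis,
         max_excluded_fraction = max_excluded_fraction),
    class = "filter_recipe")
}

#' @rdname filter_recipe
#' @param name one of `"pbmc"`, `"hca_bm"`, `"moca"` — the shipped presets
#'   for the three public atlases commonly used with this algorithm family.
#' @export
recipe_preset <- function(name = c("pbmc", "hca_bm", "moca")) {
  name <- match.arg(name)
  switch(name,
    pbmc = filter_recipe(
      excluded_gene_names = c("IGHMBP2", "IGLL1", "IGLL5", "IGLON5",
                              "NEAT1", "TMSB10", "TMSB4X"),
      exclude_mitochondrial = TRUE,
      min_cell_umis = 800, max_cell_umis = 8000,
      max_excluded_fraction = 0.1),
    hca_bm = filter_recipe(
      excluded_gene_names = c("MALAT1", "XIST"),
      exclude_mitochondrial = TRUE,
      min_cell_umis = 800, max_cell_umis = 25000,
      max_excluded_fraction = 0.3),
    moca = filter_recipe(
      excluded_gene_names = c(
        "MALAT1", "NEAT1",
        "1700007G11Rik", "1700019B21Rik", "Cmtm8", "Col4a4", "Fem1b",
        "Gm11375", "Gm28826", "Gm43298", "Kyat3", "Lancl2", "Minpp1",
        "Olfr1062", "Parn", "Poldip3", "Sirpb1b", "Syt16", "Vmn2r-ps49"),
      exclude_mitochondrial = TRUE,
      min_cell_umis = 300, max_cell_umis = 3000,
      max_excluded_fraction = 0.2))
}

#' @rdname filter_recipe
#' @param path a YAML file holding the recipe fields.
#' @export
read_filter_recipe <- function(path) {
  y <- yaml::read_yaml(path)
  filter_recipe(
    excluded_gene_names = y$excluded_gene_names %||% character(),
    exclude_mitochondrial = y$exclude_mitochondrial %||% TRUE,
    min_cell_umis = y$min_cell_umis %||% 0,
    max_cell_umis = y$max_cell_umis %||% Inf,
    max_excluded_fraction = y$max_excluded_fraction %||% 1)
}

#' @rdname filter_recipe
#' @param recipe a `filter_recipe`.
#' @export
write_filter_recipe <- function(recipe, path) {
  r <- unclass(recipe)
  if (is.infinite(r$max_cell_umis)) r$max_cell_umis <- .Machine$integer.max
  yaml::write_yaml(r, path)
  invisible(path)
}

is_mito_gene <- function(gene_ids) {
  startsWith(toupper(gene_ids), "MT-")
}

#' Apply a filter recipe to a UMI matrix
#'
#' @param m a cells x genes UMI matrix.
#' @param recipe a [filter_recipe()].
#' @return a list with `matrix` (the filtered UMI matrix) and `report`, a
#'   one-row tibble of exact removal counts plus the removed identifiers as
#'   list columns.
#' @export
apply_filter_recipe <- function(m, recipe) {
  validate_umi_matrix(m)
  gene_tot <- Matrix::colSums(m)
  excluded <- colnames(m) %in% recipe$excluded_gene_names
  if (recipe$exclude_mitochondrial) excluded <- excluded | is_mito_gene(colnames(m))
  all_zero <- gene_tot == 0
  gene_removed <- excluded | all_zero
  cell_tot <- Matrix::rowSums(m)
  excl_umis <- if (any(gene_removed)) {
    Matrix::rowSums(m[, gene_removed, drop = FALSE])
  } else {
    rep(0, nrow(m))
  }
  excl_frac <- ifelse(cell_tot > 0, excl_umis / cell_tot, 0)
  cell_removed <- cell_tot < recipe$min_cell_umis |
    cell_tot > recipe$max_cell_umis |
    excl_frac > recipe$max_excluded_fraction
  if (all(cell_removed)) {
    stop("recipe removes every cell; review the UMI bounds and exclusion list",
         call. = FALSE)
  }
  out <- m[!cell_removed, !gene_removed, drop = FALSE]
  report <- tibble::tibble(
    n_genes_in = ncol(m),
    n_genes_kept = ncol(out),
    n_genes_removed = sum(gene_removed),
    n_genes_all_zero = sum(all_zero),
    n_genes_excluded = sum(excluded),
    n_cells_in = nrow(m),
    n_cells_kept = nrow(out),
    n_cells_removed = sum(cell_removed),
    n_cells_low_umis = sum(cell_tot < recipe$min_cell_umis),
    n_cells_high_umis = sum(cell_tot > recipe$max_cell_umis),
    n_cells_excluded_fraction = sum(excl_frac > recipe$max_excluded_fraction),
    removed_genes = list(colnames(m)[gene_removed]),
    removed_cells = list(rownames(m)[cell_removed]))
  list(matrix = out, report = report)
}
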