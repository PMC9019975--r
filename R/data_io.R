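#' Construct and validate a UMI matrix
#'
#' The package's central container is a sparse `dgCMatrix` of non-negative
#' integer UMI counts, oriented cells x genes, with unique cell barcodes as
#' row names and unique gene identifiers as column names.
#'
#' @param counts a matrix or sparse Matrix of non-negative integer counts,
#'   cells in rows, genes in columns.
#' @param cell_ids,gene_ids character vectors of unique identifiers; taken
#'   from `dimnames(counts)` when omitted.
#' @return a validated `dgCMatrix`, cells x genes.
#' @export
umi_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (!is.null(cell_ids)) rownames(m) <- cell_ids
  if (!is.null(gene_ids)) colnames(m) <- gene_ids
  validate_umi_matrix(m)
  m
}

#' @rdname umi_matrix
#' @param m a candidate UMI matrix.
#' @export
validate_umi_matrix <- function(m) {
  assert_that(methods::is(m, "sparseMatrix"), "counts must be a sparse Matrix")
  assert_that(nrow(m) > 0 && ncol(m) > 0, "UMI matrix is empty")
  bad <- which(m@x < 0 | m@x != round(m@x))
  if (length(bad)) {
    stop(sprintf("non-integer or negative count (first offending value %g)",
                 m@x[bad[1]]), call. = FALSE)
  }
  assert_that(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
              "cell ids must be present and unique")
  assert_that(!is.null(colnames(m)) && !anyDuplicated(colnames(m)),
              "gene ids must be present and unique")
  invisible(m)
}

#' Read a UMI matrix from disk
#'
#' Supports the 10x-style Matrix Market directory layout (`matrix.mtx` plus
#' `barcodes.tsv` and `features.tsv`/`genes.tsv`, optionally gzipped, both
#' the 2- and 3-column feature dialects) and an HDF5 container following the
#' AnnData on-disk layout (`X`, `obs`, `var`). Counts are returned cells x
#' genes regardless of on-disk orientation. HDF5 access is bridged through
#' the system `python` with the `anndata` library.
#'
#' @param path directory (for `mtx_dir`) or `.h5ad` file (for `h5`).
#' @param format `"mtx_dir"` or `"h5"`; guessed from `path` by default.
#' @return a cells x genes sparse UMI matrix.
#' @export
load_umi_matrix <- function(path, format = c("guess", "mtx_dir", "h5")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path)) "mtx_dir" else "h5"
  }
  if (format == "mtx_dir") load_mtx_dir(path) else load_h5ad(path)
}

#' Write a UMI matrix to disk
#'
#' @param m a cells x genes UMI matrix.
#' @inheritParams load_umi_matrix
#' @return `path`, invisibly.
#' @export
save_umi_matrix <- function(m, path, format = c("mtx_dir", "h5")) {
  format <- match.arg(format)
  validate_umi_matrix(m)
  if (format == "mtx_dir") save_mtx_dir(m, path) else save_h5ad(m, path)
  invisible(path)
}

find_one <- function(dir, names) {
  for (nm in names) {
    f <- file.path(dir, nm)
    if (file.exists(f)) return(f)
  }
  stop(sprintf("none of [%s] found in %s", paste(names, collapse = ", "), dir),
       call. = FALSE)
}

load_mtx_dir <- function(path) {
  assert_that(dir.exists(path), sprintf("no such directory: %s", path))
  mtx <- find_one(path, c("matrix.mtx", "matrix.mtx.gz"))
  bc <- find_one(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  ft <- find_one(path, c("features.tsv", "features.tsv.gz",
                         "genes.tsv", "genes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  if (length(m@x) && any(m@x != round(m@x))) {
    k <- which(m@x != round(m@x))[1]
    stop(sprintf("matrix contains non-integer value %g", m@x[k]),
         call. = FALSE)
  }
  cells <- read.delim(bc, header = FALSE, colClasses = "character")[[1]]
  feat <- read.delim(ft, header = FALSE, colClasses = "character")
  genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  genes <- make.unique(genes)
  # 10x writes genes x cells; accept either orientation
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stop("matrix dimensions match neither barcodes x features nor its transpose",
         call. = FALSE)
  }
  umi_matrix(m, cell_ids = cells, gene_ids = genes)
}

save_mtx_dir <- function(m, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  # conventional genes x cells orientation on disk
  Matrix::writeMM(Matrix::t(m), file.path(path, "matrix.mtx"))
  writeLines(rownames(m), file.path(path, "barcodes.tsv"))
  write.table(data.frame(id = colnames(m), name = colnames(m),
                         type = "Gene Expression"),
              file.path(path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

python_bin <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  assert_that(nzchar(bin),
              "HDF5 support needs a system `python` with the anndata library")
  bin
}

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  on.exit(unlink(f))
  writeLines(code, f)
  out <- suppressWarnings(system2(python_bin(), f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    stop("python/anndata bridge failed:\n", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  invisible(out)
}

load_h5ad <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  tmp <- tempfile("h5_bridge_")
  on.exit(unlink(tmp, recursive = TRUE))
  run_python(c(
    "import anndata, scipy.io, scipy.sparse, os",
    sprintf("a = anndata.read_h5ad(%s)", deparse(path)),
    sprintf("os.makedirs(%s, exist_ok=True)", deparse(tmp)),
    "x = scipy.sparse.csc_matrix(a.X)",
    sprintf("scipy.io.mmwrite(os.path.join(%s, 'matrix.mtx'), x.T)", deparse(tmp)),
    sprintf("open(os.path.join(%s, 'barcodes.tsv'), 'w').write('\\n'.join(map(str, a.obs_names)) + '\\n')", deparse(tmp)),
    sprintf("open(os.path.join(%s, 'genes.tsv'), 'w').write('\\n'.join(map(str, a.var_names)) + '\\n')", deparse(tmp))
  ))
  load_mtx_dir(tmp)
}

save_h5ad <- function(m, path) {
  tmp <- tempfile("h5_bridge_")
  on.exit(unlink(tmp, recursive = TRUE))
  save_mtx_dir(m, tmp)
  run_python(c(
    "import anndata, scipy.io, scipy.sparse, pandas as pd, os",
    sprintf("d = %s", deparse(tmp)),
    "x = scipy.io.mmread(os.path.join(d, 'matrix.mtx')).T.tocsr()",
    "obs = [l.strip() for l in open(os.path.join(d, 'barcodes.tsv'))]",
    "var = [l.strip().split('\\t')[0] for l in open(os.path.join(d, 'features.tsv'))]",
    "a = anndata.AnnData(X=x, obs=pd.DataFrame(index=obs), var=pd.DataFrame(index=var))",
    sprintf("a.write_h5ad(%s)", deparse(path))
  ))
  invisible(path)
}

#' Per-cell size bookkeeping
#'
#' Metacell sizes are measured in total UMIs. To stop a few very deep cells
#' from dominating the size budget, per-cell totals are capped at twice the
#' median: `u_capped = min(u, 2 * median(u))`. The size window around the
#' target is `U_low = U_targ / 2`, `U_high = 2 * U_targ`.
#'
#' @param u per-cell total UMIs (or a UMI matrix, in which case row sums are
#'   taken).
#' @param target_umis target metacell size `U_targ` in UMIs (default 160000).
#' @return an object of class `cell_sizes`: list with `u`, `u_capped`,
#'   `U_targ`, `U_low`, `U_high`.
#' @export
cell_sizes <- function(u, target_umis = 160000) {
  if (methods::is(u, "Matrix") || is.matrix(u)) u <- Matrix::rowSums(u)
  u <- as.numeric(u)
  structure(
    list(u = u,
         u_capped = pmin(u, 2 * stats::median(u)),
         U_targ = target_umis,
         U_low = target_umis / 2,
         U_high = 2 * target_umis),
    class = "cell_sizes")
}
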