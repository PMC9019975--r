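#' Select feature genes for one pile
#'
#' Computed on cells downsampled to a common total. A gene is a feature iff
#' it (a) is not forbidden, (b) has normalized variance (variance/mean) at
#' least 0.1 above the median normalized variance of the (up to) 100 genes
#' with the most similar mean expression, (c) has at least 50 total UMIs in
#' the pile, and (d) has at least 4 UMIs in each of at least 3 cells.
#'
#' @param m downsampled cells x genes UMI matrix of one pile.
#' @param forbidden character vector of gene names never to select.
#' @param delta normalized-variance excess over the local median (0.1).
#' @param min_total_umis,min_high_umis,min_high_cells thresholds (50, 4, 3).
#' @param n_similar size of the similar-expression reference set (100).
#' @return an object of class `feature_selection`: list with
#'   `feature_genes` and a per-gene `diagnostics` tibble.
#' @export
select_features <- function(m, forbidden = character(), delta = 0.1,
                            min_total_umis = 50, min_high_umis = 4,
                            min_high_cells = 3, n_similar = 100) {
  assert_that(nrow(m) >= 2, "a pile needs at least 2 cells")
  tot <- Matrix::colSums(m)
  mu <- tot / nrow(m)
  v <- col_var_sparse(m)
  nv <- ifelse(mu > 0, v / mu, 0)
  med <- local_median(mu, nv, n_similar)
  n_high <- col_n_at_least(m, min_high_umis)
  ok <- !(colnames(m) %in% forbidden) &
    nv >= med + delta &
    tot >= min_total_umis &
    n_high >= min_high_cells
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    stop("no feature genes pass the selection thresholds; relax them or treat this pile as unpartitionable",
         call. = FALSE)
  }
  structure(
    list(feature_genes = colnames(m)[ok],
         forbidden_genes = forbidden,
         diagnostics = tibble::tibble(
           gene = colnames(m), total_umis = tot, mean = mu,
           normalized_variance = nv, local_median = med,
           n_cells_high = as.integer(n_high), feature = ok)),
    class = "feature_selection")
}

# median normalized variance of the <= n genes closest in mean expression
# (self excluded): exact sliding window over the mean-sorted order.
local_median <- function(mu, nv, n = 100) {
  G <- length(mu)
  ord <- order(mu)
  smu <- mu[ord]
  snv <- nv[ord]
  out <- numeric(G)
  k <- min(n, G - 1)
  for (pos in seq_len(G)) {
    lo <- pos
    hi <- pos
    while (hi - lo < k) {
      d_lo <- if (lo > 1) smu[pos] - smu[lo - 1] else Inf
      d_hi <- if (hi < G) smu[hi + 1] - smu[pos] else Inf
      if (d_lo <= d_hi) lo <- lo - 1 else hi <- hi + 1
    }
    idx <- setdiff(lo:hi, pos)
    out[pos] <- stats::median(snv[idx])
  }
  res <- numeric(G)
  res[ord] <- out
  res
}

#' Choose the neighbour budget K
#'
#' K is the median number of cells needed to reach the target metacell size:
#' `ceil(U_targ / median(u))`, at least 1.
#'
#' @param u per-cell total UMIs.
#' @param target_umis target metacell size in UMIs.
#' @export
choose_K <- function(u, target_umis = 160000) {
  assert_that(length(u) > 0, "empty pile")
  max(1L, as.integer(ceiling(target_umis / stats::median(u))))
}

#' Build the balanced K-nn cell graph of a pile
#'
#' Cell-cell similarity is the Pearson correlation of `log2(count + 1)`
#' over the feature genes. Similarities are converted per cell to outgoing
#' ranks (most similar neighbour highest: `n_cells - position`), balanced
#' as the geometric mean with the transposed rank, pre-pruned so that only
#' each cell's top `ceil(sqrt(10) * K)` balanced candidates survive, then
#' capped at `3K` strongest incoming and `K` strongest outgoing edges per
#' cell. Weights are the balanced ranks scaled to `(0, 1]`. Cells with no
#' feature UMIs (or no variance over features) become isolated, flagged
#' nodes.
#'
#' @param m downsampled cells x features UMI matrix (feature genes only).
#' @param K neighbour budget from [choose_K()].
#' @return an object of class `cell_graph`: list with `w` (n x n sparse
#'   directed weight matrix, `w[i, j]` the weight of edge i -> j), `K`,
#'   `isolated` (logical), `cell_ids`.
#' @export
build_balanced_knn <- function(m, K) {
  n <- nrow(m)
  assert_that(n >= 2 && ncol(m) >= 1, "need >= 2 cells and >= 1 feature")
  x <- as.matrix(m)
  lx <- log2(x + 1)
  spread <- apply(lx, 1, function(r) max(r) - min(r))
  live <- Matrix::rowSums(m) > 0 & spread > 0
  w <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(n, n),
                            dimnames = list(rownames(m), rownames(m)))
  if (sum(live) >= 2) {
    S <- fast_cor_rows(lx[live, , drop = FALSE])
    el <- cpp_balanced_knn(S, as.integer(ceiling(sqrt(10) * K)),
                           as.integer(3L * K), as.integer(K))
    idx <- which(live)
    w <- Matrix::sparseMatrix(i = idx[el$i], j = idx[el$j], x = el$w,
                              dims = c(n, n),
                              dimnames = list(rownames(m), rownames(m)))
  }
  structure(
    list(w = methods::as(w, "CsparseMatrix"), K = K, n = n,
         isolated = !live, cell_ids = rownames(m)),
    class = "cell_graph")
}

#' Edge list of a cell graph
#' @param g a `cell_graph`.
#' @return tibble with `src_cell`, `targ_cell`, `weight`.
#' @export
graph_edges <- function(g) {
  s <- Matrix::summary(g$w)
  tibble::tibble(src_cell = g$cell_ids[s$i],
                 targ_cell = g$cell_ids[s$j],
                 weight = s$x)
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("balanced K-nn cell graph: %d cells, %d edges, K = %d, %d isolated\n",
              x$n, length(x$w@x), x$K, sum(x$isolated)))
  invisible(x)
}
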