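#' Downsample cells to a common UMI total
#'
#' Each cell with more than `target` total UMIs is replaced by a uniform
#' random subsample of exactly `target` of its molecules, drawn without
#' replacement (multivariate hypergeometric over its gene counts); cells at
#' or below the target are left untouched. Deterministic given `seed`.
#'
#' @param m a cells x genes UMI matrix.
#' @param target target per-cell total (UMIs), `>= 1`.
#' @param seed integer RNG seed.
#' @return a UMI matrix of identical shape; no count ever increases.
#' @export
downsample_cells <- function(m, target, seed = 1L) {
  assert_that(target >= 1, "target must be >= 1")
  mt <- methods::as(Matrix::t(m), "CsparseMatrix")  # columns are cells
  set.seed(seed)
  new_x <- cpp_downsample_csc(mt@p, mt@x, target)
  mt@x <- new_x
  out <- Matrix::t(Matrix::drop0(mt))
  methods::as(out, "CsparseMatrix")
}

#' Default downsampling target for a pile
#'
#' "The same size" must be attainable by most cells, so the default target
#' is the 5th percentile of per-cell totals, clipped to `[500, U_targ]`.
#'
#' @param u per-cell total UMIs.
#' @param target_umis upper clip (the target metacell size).
#' @return an integer UMI target.
#' @export
default_downsample_target <- function(u, target_umis = 160000) {
  as.integer(max(1, round(clamp(quantile(u, 0.05, names = FALSE), 500,
                                target_umis))))
}
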