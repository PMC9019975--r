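# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-pile seed derivation: mixes the master seed with a phase
# tag and a pile index so parallel and serial execution see identical RNG
# streams. Kept below 2^31 - 1.
derive_seed <- function(seed, phase, pile = 0L) {
  phase_code <- sum(utf8ToInt(phase)) %% 997L
  val <- (as.double(seed) * 48271 + phase_code * 30269 + as.double(pile) * 49393)
  as.integer(val %% 2147483562) + 1L
}

# Per-gene (column) maximum of a cells x genes dgCMatrix.
col_max_sparse <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  cpp_col_max(m@p, m@x, ncol(m))
}

# Per-gene count of cells with >= `at_least` UMIs.
col_n_at_least <- function(m, at_least) {
  m <- methods::as(m, "CsparseMatrix")
  cpp_col_n_at_least(m@p, m@x, ncol(m), at_least)
}

# Sample variance per column of a sparse matrix (denominator n - 1).
col_var_sparse <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(NA_real_, ncol(m)))
  mu <- Matrix::colSums(m) / n
  ex2 <- Matrix::colSums(m^2) / n
  (ex2 - mu^2) * n / (n - 1)
}

# Pearson correlation with zero-variance columns mapped to 0 (not NA).
safe_cor <- function(x) {
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# Row-row Pearson correlation via BLAS: standardize rows, crossprod.
# Zero-variance rows correlate 0; diagonal is 1.
fast_cor_rows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  ok <- ss > 0
  xc[ok, ] <- xc[ok, , drop = FALSE] / ss[ok]
  xc[!ok, ] <- 0
  r <- tcrossprod(xc)
  diag(r) <- 1
  r
}
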