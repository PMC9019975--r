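# Shared fixtures: tiny matrices, hand-built graphs, and independent
# oracles used across test files.

library(Matrix)

# a tiny deterministic UMI matrix with named cells/genes
tiny_umis <- function(n_cells = 3, n_genes = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes,
              dimnames = list(paste0("c", seq_len(n_cells)),
                              paste0("g", seq_len(n_genes))))
  umi_matrix(m)
}

# build a cell_graph directly from a dense directed weight matrix
graph_from_dense <- function(w, K = nrow(w)) {
  n <- nrow(w)
  ids <- paste0("c", seq_len(n))
  sw <- methods::as(methods::as(Matrix::Matrix(w, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  dimnames(sw) <- list(ids, ids)
  structure(list(w = sw, K = K, n = n, isolated = rep(FALSE, n),
                 cell_ids = ids),
            class = "cell_graph")
}

# two equal cliques with optional cross-edge noise, directed symmetric
two_clique_graph <- function(n_per = 6, w_in = 1, w_cross = 0, seed = NULL) {
  n <- 2 * n_per
  w <- matrix(w_cross, n, n)
  w[seq_len(n_per), seq_len(n_per)] <- w_in
  w[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- w_in
  if (!is.null(seed)) {
    set.seed(seed)
    jitter <- matrix(runif(n * n, 0, 0.05), n, n)
    w <- w + jitter
  }
  diag(w) <- 0
  graph_from_dense(w)
}

# Independent score oracle: direct transcription of the formulas, dense,
# one node at a time (no sharing with the package implementation).
oracle_score <- function(w, mc, floor_log = -10) {
  w <- as.matrix(w)
  n <- nrow(w)
  sizes <- tabulate(mc, max(mc))
  fl <- function(num, den) {
    if (den > 0 && num > 0) max(log(num / den), floor_log) else floor_log
  }
  total <- 0
  for (v in seq_len(n)) {
    same <- mc == mc[v]
    punif <- sizes[mc[v]] / n
    total <- total +
      fl(sum(w[v, same]), sum(w[v, ])) - log(punif) +
      fl(sum(w[same, v]), sum(w[, v])) - log(punif)
  }
  total / (2 * n)
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxval + 1L)) {
      rec(c(prefix, v), max(maxval, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# enumerate all 2-part partitions (plus the trivial 1-part) of 1..n
all_bipartitions <- function(n) {
  parts <- list(rep(1L, n))
  for (code in seq_len(2^(n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    parts[[length(parts) + 1L]] <- bits + 1L
  }
  parts
}

# a small random weighted directed graph
random_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < p_edge)
  diag(w) <- 0
  # ensure no node is fully disconnected
  for (v in seq_len(n)) {
    if (sum(w[v, ]) == 0) w[v, (v %% n) + 1] <- runif(1)
    if (sum(w[, v]) == 0) w[(v %% n) + 1, v] <- runif(1)
  }
  graph_from_dense(w)
}

# small multinomial population sampled at fixed depths from one profile
one_state_matrix <- function(n_cells, n_genes, depth = 1000, seed = 1) {
  g <- generate_states(1, n_genes, n_cells,
                       depth_distribution = depth_lognormal(depth, 0.25,
                                                            depth / 2,
                                                            depth * 4),
                       separation = 1, seed = seed, n_micro = 0,
                       n_sporadic = 0)
  g$matrix
}
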