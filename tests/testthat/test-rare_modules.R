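# independent oracle: enumerate every hclust subtree, keep the qualifying
# ones, and reduce to maximal sets by containment
oracle_modules <- function(r2, min_genes = 4, min_r2 = 0.1) {
  hc <- hclust(as.dist(1 - r2), method = "ward.D2")
  subtrees <- list()
  collect <- function(node) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    leaves <- c(collect(kids[1]), collect(kids[2]))
    subtrees[[length(subtrees) + 1L]] <<- leaves
    leaves
  }
  collect(nrow(hc$merge))
  qual <- Filter(function(idx) {
    sub <- r2[idx, idx]
    length(idx) >= min_genes &&
      (sum(sub) - length(idx)) / (length(idx) * (length(idx) - 1)) >= min_r2
  }, subtrees)
  maximal <- Filter(function(a) {
    !any(vapply(qual, function(b)
      length(a) < length(b) && all(a %in% b), logical(1)))
  }, qual)
  lapply(maximal, function(idx) sort(rownames(r2)[idx]))
}

block_r2 <- function(blocks, n_noise, hi = 0.9, seed = 1) {
  set.seed(seed)
  n <- sum(blocks) + n_noise
  r2 <- matrix(runif(n * n, -0.05, 0.05), n, n)
  r2 <- (r2 + t(r2)) / 2
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(b)
    r2[idx, idx] <- hi
    at <- at + b
  }
  diag(r2) <- 1
  dimnames(r2) <- list(paste0("g", 1:n), paste0("g", 1:n))
  r2
}

test_that("rare genes require both the cell-fraction and abundance thresholds", {
  n <- 10000
  mt <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                             dims = c(n, 3))
  mt[1:5, 1] <- c(8, 2, 1, 1, 1)    # 5 cells, max 8: rare
  mt[1:200, 2] <- 3                 # 2% of cells: fraction fails
  mt[1:3, 3] <- 5                   # 3 cells, max 5: abundance fails
  dimnames(mt) <- list(paste0("c", 1:n), c("rare", "common", "dim"))
  m <- umi_matrix(mt)
  expect_identical(find_rare_genes(m), "rare")
})

test_that("second-order correlation is symmetric, unit-diagonal, and 1 for identical genes", {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   1, 2, 3, 4, 5,
                   5, 1, 4, 2, 3), 3, 5, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  r2 <- second_order_correlation(expr)
  expect_equal(r2["a", "b"], 1)
  expect_equal(diag(r2), setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(r2, t(r2))
  # zero-variance gene: correlations defined as 0
  expr0 <- rbind(expr, d = rep(2, 5))
  r <- metacellr:::safe_cor(t(log2(expr0 + 1)))
  expect_true(all(r["d", c("a", "b", "c")] == 0))
})

test_that("candidate modules match the exhaustive subtree oracle", {
  # no correlation: nothing qualifies
  expect_length(candidate_modules(diag(10)), 0L)
  # one 5-gene block
  r2 <- block_r2(5, 20, seed = 2)
  got <- candidate_modules(r2)
  expect_equal(lapply(got, sort), oracle_modules(r2))
  expect_length(got, 1L)
  expect_setequal(got[[1]], paste0("g", 1:5))
  # two disjoint blocks
  r2b <- block_r2(c(5, 6), 15, seed = 3)
  gotb <- candidate_modules(r2b)
  expect_equal(lapply(gotb, function(x) sort(unname(x))), oracle_modules(r2b))
  expect_length(gotb, 2L)
  expect_length(intersect(gotb[[1]], gotb[[2]]), 0L)
  # random matrices: oracle equivalence as a property
  for (s in 4:8) {
    r2r <- block_r2(sample(3:7, 1), sample(5:25, 1), hi = runif(1, 0.3, 0.95),
                    seed = s)
    expect_equal(lapply(candidate_modules(r2r), function(x) sort(unname(x))),
                 oracle_modules(r2r))
  }
})

test_that("module expansion enforces the cell bounds and discards degenerate modules", {
  g <- generate_states(2, 600, 20000, separation = 2, seed = 12)
  pr <- plant_rare_type(g$matrix, g$truth, 8 / 20000, module_size = 5,
                        enrichment = 50, seed = 2)
  mod8 <- expand_module(pr$truth$rare_modules[[1]]$genes, pr$matrix,
                        pile_size = 10000)
  expect_true(mod8$discarded)
  expect_equal(mod8$reason, "too_few")
  # a module expressed by a large share of cells is too common
  common_gene <- names(which.max(Matrix::colSums(g$matrix > 0)))
  modc <- expand_module(common_gene, g$matrix, pile_size = 10000)
  expect_true(modc$discarded)
  expect_equal(modc$reason, "too_common")
  # a healthy planted module is kept with its cells
  pr2 <- plant_rare_type(g$matrix, g$truth, 30 / 20000, module_size = 5,
                         enrichment = 50, seed = 3)
  tm <- pr2$truth$rare_modules[[1]]
  mod <- expand_module(tm$genes, pr2$matrix, pile_size = 10000)
  expect_false(mod$discarded)
  expect_gte(length(intersect(mod$cells_CM, tm$cells)), 27)
  expect_true(all(tm$genes %in% mod$expanded_genes))
})

test_that("detect_rare_modules returns disjoint planted modules and nothing on clean data", {
  clean <- one_state_matrix(5000, 400, depth = 1500, seed = 13)
  det0 <- detect_rare_modules(clean, pile_size = 5000)
  expect_length(det0$modules, 0L)

  # both planted frequencies must sit under the 1e-3 rarity cap
  g <- generate_states(2, 800, 30000, separation = 2, seed = 14)
  p1 <- plant_rare_type(g$matrix, g$truth, 20 / 30000, module_size = 5,
                        enrichment = 50, seed = 4)
  p2 <- plant_rare_type(p1$matrix, p1$truth, 28 / 30000, module_size = 5,
                        enrichment = 50, seed = 5)
  det <- detect_rare_modules(p2$matrix, pile_size = 10000)
  truth_mods <- p2$truth$rare_modules
  # each planted module is recovered by some detected module
  for (tm in truth_mods) {
    hit <- vapply(det$modules, function(md) {
      length(intersect(md$expanded_genes, tm$genes)) >= 3 &&
        length(intersect(md$cells_CM, tm$cells)) >= 0.8 * length(tm$cells)
    }, logical(1))
    expect_true(any(hit))
  }
  # all returned modules respect the size bounds and cell sets are disjoint
  for (md in det$modules) {
    expect_gte(length(md$cells_CM), 12)
    expect_lte(length(md$cells_CM), md$T_max)
  }
  all_cells <- unlist(lapply(det$modules, `[[`, "cells_CM"))
  expect_equal(anyDuplicated(all_cells), 0L)
})
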