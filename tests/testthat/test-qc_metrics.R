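test_that("inner normalized variance is 0 for identical cells, ~1 for multinomial groups, inflated by mixing", {
  mt <- matrix(rep(c(30L, 50L, 20L, 40L), each = 10), 10, 4,
               dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
  expect_equal(inner_normalized_variance(umi_matrix(mt)), 0)
  expect_true(is.na(inner_normalized_variance(umi_matrix(mt[1, , drop = FALSE]))))

  # i.i.d. multinomial: concentrates near 1 (95th percentile statistic)
  invs <- numeric(6)
  for (s in seq_len(6)) {
    m <- one_state_matrix(50, 1000, depth = 1200, seed = 300 + s)
    invs[s] <- inner_normalized_variance(m, seed = s)
  }
  expect_true(all(invs >= 0.8 & invs <= 1.6))

  # mixing two separated states is stochastically larger, pairwise
  worse <- logical(10)
  for (s in seq_len(10)) {
    g <- generate_states(2, 1000, 100,
                         depth_distribution = depth_lognormal(1200, 0.2, 800, 3000),
                         separation = 8, seed = 400 + s, n_micro = 0)
    st <- g$truth$state
    pure <- inner_normalized_variance(g$matrix[which(st == 1)[1:50], ], seed = s)
    mixed_cells <- c(which(st == 1)[1:25], which(st == 2)[1:25])
    mixed <- inner_normalized_variance(g$matrix[mixed_cells, ], seed = s)
    worse[s] <- mixed > pure
  }
  expect_gte(sum(worse), 9)
})

test_that("size-distribution matching equalizes rank-matched metacell sizes", {
  fake_sol <- function(sizes) {
    assignment <- rep(seq_along(sizes), sizes)
    structure(list(assignment = assignment,
                   cell_ids = paste0("c", seq_along(assignment)),
                   n_cells = length(assignment),
                   n_metacells = length(sizes)),
              class = "metacell_solution")
  }
  s1 <- fake_sol(c(20, 30))
  s2 <- fake_sol(c(25, 35))
  types <- list(rep("T", 50), rep("T", 60))
  adj <- match_size_distributions(list(s1, s2), types, seed = 1)
  # rank-matched sizes equal across solutions, at the minimum
  for (r in 1:2) {
    sizes_r <- adj$adjusted_cells[adj$rank == r]
    expect_equal(length(unique(sizes_r)), 1L)
  }
  expect_setequal(adj$adjusted_cells[adj$solution == 1], c(20, 30))
  expect_setequal(adj$adjusted_cells[adj$solution == 2], c(20, 30))
  # identical solutions: unchanged
  adj2 <- match_size_distributions(list(s1, s1), list(types[[1]], types[[1]]))
  expect_equal(adj2$adjusted_cells, adj2$original_cells)
  # missing type: skipped with a warning
  types3 <- list(rep("T", 50), rep("B", 60))
  w <- capture_warnings(match_size_distributions(list(s1, s2), types3))
  expect_true(any(grepl("absent", w)))
})

test_that("rare marker screening flags exclusive genes and degenerates sensibly", {
  set.seed(5)
  profiles <- matrix(rpois(40 * 30, 50), 40, 30,
                     dimnames = list(sprintf("mc_%02d", 1:40),
                                     paste0("g", 1:30)))
  profiles[, 30] <- 0L
  profiles[7, 30] <- 400L  # exclusive to metacell 7
  sol <- structure(list(n_metacells = 40,
                        profiles = umi_matrix(profiles),
                        provenance = rep("main", 40)),
                   class = "metacell_solution")
  hits <- screen_rare_marker_genes(sol)
  expect_true("g30" %in% hits$gene)
  expect_equal(hits$top_metacell[hits$gene == "g30"], 7L)
  # perfectly flat expression yields nothing
  flat <- sol
  flat$profiles <- umi_matrix(matrix(50L, 40, 5,
                                     dimnames = list(rownames(profiles),
                                                     paste0("f", 1:5))))
  expect_equal(nrow(screen_rare_marker_genes(flat)), 0L)
  # fold = 1: every gene with a strict top metacell passes
  lax <- screen_rare_marker_genes(sol, fold = 1)
  expect_gte(nrow(lax), nrow(hits))
})

test_that("AUROC is 1 for a perfectly separating gene, ~0.5 for noise, and rank-invariant", {
  set.seed(6)
  n <- 2000
  mt <- matrix(rpois(n * 4, 5), n, 4,
               dimnames = list(paste0("c", 1:n), paste0("g", 1:4)))
  pos <- 1:100
  mt[, 1] <- 0L
  mt[pos, 1] <- 10L               # perfect separator
  mt[-pos, 4] <- mt[-pos, 4] + 10L  # balance per-cell totals across labels
  m <- umi_matrix(mt)
  sol <- structure(list(assignment = ifelse(seq_len(n) %in% pos, 1L, 2L),
                        cell_ids = rownames(m)),
                   class = "metacell_solution")
  module <- list(cells_CM = rownames(m)[pos])
  res <- rare_behavior_auroc(sol, module, m)
  expect_equal(res$auroc[res$gene == "g1"], 1)
  expect_lt(abs(res$auroc[res$gene == "g3"] - 0.5), 0.05)
  # monotone transform of expression leaves AUROC unchanged
  m2 <- m
  m2[, 2] <- m[, 2] * 7
  res2 <- rare_behavior_auroc(sol, module, m2)
  expect_equal(res2$auroc[res2$gene == "g2"], res$auroc[res$gene == "g2"])
  expect_error(rare_behavior_auroc(sol, list(cells_CM = character()), m),
               "no positive")
})

test_that("module score distributions threshold at half the top group's median", {
  set.seed(7)
  n <- 300
  mt <- matrix(rpois(n * 10, 5), n, 10,
               dimnames = list(paste0("c", 1:n), paste0("g", 1:10)))
  mt[, 10] <- 0L
  grp <- rep(1:3, each = 100)
  mt[grp == 2, 10] <- 25L
  m <- umi_matrix(mt)
  module <- list(expanded_genes = "g10")
  res <- rare_score_distribution(grp, module, m)
  expect_equal(res$top_group, 2L)
  expect_equal(res$threshold, 0.5 * median(res$scores[grp == 2]))
  expect_true(all(which(grp == 2) %in% res$positives))
  # absent module genes: all zero, no positives
  res0 <- rare_score_distribution(grp, list(expanded_genes = "nope"), m)
  expect_true(all(res0$scores == 0))
  expect_length(res0$positives, 0L)
})
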