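test_that("score is 0 for a single metacell and ln 2 for two separated cliques", {
  g <- two_clique_graph(6)
  one <- compute_score(g, rep(1L, 12))
  expect_equal(one$score, 0)
  two <- compute_score(g, rep(1:2, each = 6))
  expect_equal(two$score, log(2), tolerance = 1e-12)
  expect_true(all(two$terms$pstable_out == 1))
  expect_true(all(two$terms$punif == 0.5))
})

test_that("compute_score matches the brute-force oracle on every partition of small random graphs", {
  for (seed in c(7, 19, 42)) {
    g <- random_graph(8, seed = seed)
    parts <- all_set_partitions(8)
    # spot the full enumeration: compare every 25th partition plus extremes
    idx <- unique(c(1, seq(1, length(parts), by = 25), length(parts)))
    for (k in idx) {
      mc <- parts[[k]]
      expect_equal(compute_score(g, mc)$score,
                   oracle_score(g$w, mc), tolerance = 1e-12)
    }
  }
})

test_that("score is invariant under metacell relabeling", {
  g <- random_graph(10, seed = 3)
  mc <- c(1L, 2L, 1L, 3L, 2L, 3L, 1L, 2L, 3L, 1L)
  relab <- c(3L, 1L, 2L)[mc]
  expect_equal(compute_score(g, mc)$score, compute_score(g, relab)$score)
})

test_that("seeding covers all nodes; P = 1 gives a single metacell; disconnected cliques get separated seeds", {
  g <- two_clique_graph(6)
  p1 <- seed_partition(g, 1, seed = 5)
  expect_equal(p1$n_metacells, 1L)
  expect_true(all(p1$mc == 1L))
  for (s in 1:10) {
    p2 <- seed_partition(g, 2, seed = s)
    expect_setequal(unique(p2$mc[1:6]), p2$mc[1])
    expect_setequal(unique(p2$mc[7:12]), p2$mc[7])
    expect_false(p2$mc[1] == p2$mc[7])
  }
  # P larger than |V| is clamped
  p_many <- seed_partition(g, 50, seed = 2)
  expect_true(all(p_many$mc > 0L))
})

test_that("the optimizer is monotone at lambda 0, a fixed point at the optimum, and recovers enumerated optima", {
  # fixed point: the two-clique optimum stays put
  g <- two_clique_graph(6)
  opt_mc <- rep(1:2, each = 6)
  p <- optimize_partition(g, opt_mc, seed = 1)
  expect_equal(compute_score(g, p)$score, log(2), tolerance = 1e-12)

  # monotonicity at lambda = 0 from arbitrary starts
  for (s in 1:5) {
    g <- random_graph(12, p_edge = 0.4, seed = 100 + s)
    set.seed(s)
    mc0 <- sample(1:3, 12, replace = TRUE)
    mc0 <- match(mc0, unique(mc0))  # dense labels
    p1 <- optimize_partition(g, mc0, lambda_schedule = 0, seed = s)
    expect_gte(compute_score(g, p1)$score,
               compute_score(g, mc0)$score - 1e-10)
  }

  # enumerated optimum on two-cluster instances (all bipartitions oracle)
  hits <- 0L
  n_inst <- 20L
  for (s in seq_len(n_inst)) {
    g <- two_clique_graph(6, w_in = 1, w_cross = 0.05, seed = 1000 + s)
    best <- max(vapply(all_bipartitions(12),
                       function(mc) oracle_score(g$w, mc), numeric(1)))
    p0 <- seed_partition(g, 2, seed = s)
    p <- optimize_partition(g, p0, seed = s)
    if (compute_score(g, p)$score >= best - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("max-size control dissolves oversized metacells and preserves the cover", {
  g <- two_clique_graph(10, w_in = 1, w_cross = 0.02, seed = 9)
  u <- rep(1000, 20)
  cfg <- mc2_config(target_umis = 8000)
  sizes <- cell_sizes(u, 8000)  # U_high = 16000 < 20 cells x 1000
  p <- metacellr:::new_partition(rep(1L, 20))
  res <- enforce_max_size(g, p, sizes, cfg, seed = 4)
  expect_equal(res$dissolved, 1L)
  expect_true(all(res$partition$mc > 0L))  # still a cover
  tot <- metacellr:::metacell_u_totals(res$partition$mc, sizes$u_capped)
  expect_true(all(tot < sizes$U_high))
  # below the bound: identity
  sizes_big <- cell_sizes(u, 160000)
  res2 <- enforce_max_size(g, p, sizes_big, mc2_config(), seed = 4)
  expect_identical(res2$partition$mc, p$mc)
})

test_that("connectivity control dissolves weakly joined metacells and disassociates small appendages", {
  cfg <- mc2_config()
  # two 10-cliques joined by one epsilon edge, forced into one metacell
  n <- 20
  w <- matrix(0, n, n)
  w[1:10, 1:10] <- 1
  w[11:20, 11:20] <- 1
  diag(w) <- 0
  w[10, 11] <- 1e-4
  w[11, 10] <- 1e-4
  g <- graph_from_dense(w)
  sizes <- cell_sizes(rep(1000, n), 160000)
  res <- enforce_connectivity(g, metacellr:::new_partition(rep(1L, n)),
                              sizes, cfg, seed = 2)
  expect_equal(res$n_dissolved, 1L)

  # clique metacell: untouched
  g2 <- graph_from_dense({w2 <- matrix(1, 12, 12); diag(w2) <- 0; w2})
  res2 <- enforce_connectivity(g2, metacellr:::new_partition(rep(1L, 12)),
                               cell_sizes(rep(1000, 12), 160000), cfg, 2)
  expect_equal(res2$n_dissolved, 0L)
  expect_equal(res2$n_disassociated, 0L)

  # 20-clique plus 3 mutually connected cells attached by weak edges:
  # the min cut isolates the 3-cell appendage, which is disassociated
  n3 <- 23
  w3 <- matrix(0, n3, n3)
  w3[1:20, 1:20] <- 1
  w3[21:23, 1] <- 1e-4
  w3[1, 21:23] <- 1e-4
  w3[21:23, 21:23] <- 0.5
  diag(w3) <- 0
  g3 <- graph_from_dense(w3)
  res3 <- enforce_connectivity(g3, metacellr:::new_partition(rep(1L, n3)),
                               cell_sizes(rep(1000, n3), 160000), cfg, 2)
  expect_equal(res3$n_disassociated, 3L)
  expect_setequal(which(res3$partition$mc == 0L), 21:23)
  expect_true(all(res3$partition$mc[1:20] > 0L))
})

test_that("min-size control dissolves small metacells but spares marker metacells at half the bound", {
  set.seed(11)
  # 10 clique groups of 20 cells plus one small group of 12 carrying a
  # private marker gene (the 8-fold-over-the-metacell-mean test needs a
  # realistic number of metacells to be able to trigger)
  n_groups <- 10
  n <- 30 * n_groups + 12
  grp <- rep(seq_len(n_groups + 1), c(rep(30, n_groups), 12))
  w <- matrix(0.001, n, n)
  for (k in seq_len(n_groups + 1)) w[grp == k, grp == k] <- 1
  diag(w) <- 0
  g <- graph_from_dense(w)
  counts <- matrix(rpois(n * 30, 5), n, 30,
                   dimnames = list(paste0("c", 1:n), paste0("g", 1:30)))
  counts[grp == n_groups + 1, 30] <- 60  # exclusive marker, ~11-fold over mean
  counts[grp != n_groups + 1, 30] <- 0
  counts <- umi_matrix(counts)
  u <- Matrix::rowSums(counts)
  cfg <- mc2_config(lambda_schedule = 0)
  expect_true(tail(metacellr:::marker_metacells(counts, grp), 1))
  expect_false(any(head(metacellr:::marker_metacells(counts, grp), -1)))
  # U_low between the small group total and twice it: with the marker the
  # group survives at half the bound, without it it dissolves
  small_tot <- sum(pmin(u, 2 * median(u))[grp == n_groups + 1])
  sizes <- cell_sizes(u, 3 * small_tot)
  p <- metacellr:::new_partition(grp)
  res <- enforce_min_size(g, p, counts, sizes, cfg, seed = 3)
  expect_equal(res$partition$n_metacells, n_groups + 1L)
  counts2 <- counts
  counts2[grp == n_groups + 1, 30] <- 0
  res2 <- enforce_min_size(g, p, counts2, sizes, cfg, seed = 3)
  expect_equal(res2$partition$n_metacells, n_groups)
  # fewer than 12 cells always dissolves
  p3 <- metacellr:::new_partition(c(grp[seq_len(n - 2)], grp[n - 2], grp[n - 2]))
  res3 <- enforce_min_size(g, p3, counts, cell_sizes(u, 2000), cfg, seed = 3)
  expect_true(all(tabulate(res3$partition$mc) >= 12 |
                    tabulate(res3$partition$mc) == 0))
})

test_that("partition_pile yields size-bounded, covering partitions on planted states", {
  g <- generate_states(4, 600, 1200,
                       depth_distribution = depth_lognormal(800, 0.3, 400, 3000),
                       separation = 4, seed = 17, n_micro = 0)
  m <- g$matrix
  ds <- downsample_cells(m, 700, seed = 1)
  fs <- select_features(ds)
  sizes <- cell_sizes(Matrix::rowSums(m), 16000)
  K <- choose_K(sizes$u, sizes$U_targ)
  gr <- build_balanced_knn(ds[, fs$feature_genes], K)
  cfg <- mc2_config(target_umis = 16000)
  res <- partition_pile(gr, ds, sizes, cfg, seed = 5)
  p <- res$partition
  expect_equal(length(p$mc), 1200L)
  # bookkeeping: assigned + outliers = pile
  expect_equal(sum(p$mc > 0L) + sum(p$mc == 0L), 1200L)
  tot <- metacellr:::metacell_u_totals(p$mc, res$sizes$u_capped)
  if (length(res$warnings) == 0) {
    expect_true(all(tot < res$sizes$U_high))
    expect_true(all(tot > 0.5 * res$sizes$U_low))
  }
  # purity against planted states
  purity <- vapply(seq_len(p$n_metacells), function(k) {
    tb <- table(g$truth$state[p$mc == k])
    max(tb) / sum(tb)
  }, numeric(1))
  expect_gte(mean(purity >= 0.9), 0.9)
})
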