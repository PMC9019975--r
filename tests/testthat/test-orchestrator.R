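test_that("pile size arithmetic follows the expected-metacells rule with hard clamps", {
  expect_equal(choose_pile_size(1e6, 160000, 2000, 100), 10000L)  # 8000 clamped up
  expect_equal(choose_pile_size(1e6, 160000, 2000, 50), 10000L)
  expect_equal(choose_pile_size(1e6, 160000, 500, 100), 30000L)   # 32000 clamped down
  expect_equal(choose_pile_size(1e6, 160000, 1000, 100), 16000L)
  # MOCA-style choice: 50 metacells per pile halves the raw size
  expect_equal(50 * 160000 / 1000, 8000)
})

test_that("random piles are disjoint, exhaustive, near-equal and respect the bounds", {
  piles <- metacellr:::make_random_piles(44000, 10000, seed = 3)
  expect_equal(sort(unname(unlist(piles))), 1:44000)
  sz <- lengths(piles)
  expect_true(all(sz >= 10000 & sz <= 30000))
  expect_lte(max(sz) - min(sz), 1)
  # small datasets are one pile
  expect_length(metacellr:::make_random_piles(5000, 10000, seed = 1), 1L)
  expect_length(metacellr:::make_random_piles(16000, 10000, seed = 1), 1L)
})

# one moderate dataset shared by the remaining blocks
gsmall <- generate_states(3, 700, 3000,
                          depth_distribution = depth_lognormal(800, 0.4, 300, 4000),
                          separation = 4, seed = 61)
cfg_small <- mc2_config(target_umis = 12000)
sol_small <- run_mc2(gsmall$matrix, cfg_small, seed = 7)

test_that("run_mc2 conserves cells and is deterministic given the seed", {
  expect_equal(sum(sol_small$metacell_n_cells) + sol_small$n_outliers,
               sol_small$n_cells)
  expect_equal(sort(unique(sol_small$assignment[sol_small$assignment > 0L])),
               seq_len(sol_small$n_metacells))
  sol_again <- run_mc2(gsmall$matrix, cfg_small, seed = 7)
  expect_identical(sol_small$assignment, sol_again$assignment)
  expect_identical(as.matrix(sol_small$profiles), as.matrix(sol_again$profiles))
  # pooled profiles are exact column sums of member cells
  for (k in c(1L, sol_small$n_metacells)) {
    expect_equal(as.numeric(sol_small$profiles[k, ]),
                 as.numeric(Matrix::colSums(
                   gsmall$matrix[sol_small$assignment == k, , drop = FALSE])))
  }
})

test_that("a dataset fitting one pile reproduces the direct basic algorithm bit for bit", {
  sol_direct <- run_direct(gsmall$matrix, cfg_small, seed = 7)
  expect_identical(sol_small$assignment, sol_direct$assignment)
  expect_identical(as.matrix(sol_small$profiles),
                   as.matrix(sol_direct$profiles))
  expect_identical(sol_small$provenance, sol_direct$provenance)
})

test_that("tidy, glance, export and autoplot present the solution faithfully", {
  td <- tidy(sol_small)
  expect_equal(nrow(td), 3000L)
  expect_equal(sum(is.na(td$metacell)), sol_small$n_outliers)
  gl <- glance(sol_small)
  expect_equal(gl$n_metacells, sol_small$n_metacells)
  d <- withr::local_tempdir()
  export_solution(sol_small, d)
  map <- read.delim(file.path(d, "cell_metacell.tsv"))
  expect_equal(nrow(map), 3000L)
  expect_equal(sum(map$metacell_id == -1), sol_small$n_outliers)
  back <- load_umi_matrix(file.path(d, "metacell_umis"))
  expect_equal(unname(as.matrix(back)), unname(as.matrix(sol_small$profiles)))
  manifest <- jsonlite::read_json(file.path(d, "run_manifest.json"))
  expect_equal(manifest$n_cells, 3000L)
  expect_s3_class(autoplot(sol_small), "ggplot")
})

test_that("the metagroup phase groups preliminary metacells into state-coherent cell-budgeted groups", {
  prelim <- preliminary_phase(gsmall$matrix, cfg_small, seed = 7,
                              pile_size = 3000)
  expect_true(all(prelim$mc > 0L))  # full cover
  cfg_mg <- cfg_small
  cfg_mg$metagroup_target_cells <- 1000
  groups <- metagroup_phase(prelim$mc, gsmall$matrix, cfg_mg, seed = 7,
                            pile_size = 3000)
  expect_equal(length(groups), max(prelim$mc))
  per_group_cells <- tabulate(groups[prelim$mc])
  expect_true(all(per_group_cells <= 2 * 1000))
  # metagroups align with planted states
  grp_of_cell <- groups[prelim$mc]
  purity <- vapply(seq_len(max(groups)), function(g) {
    tb <- table(gsmall$truth$state[grp_of_cell == g])
    max(tb) / sum(tb)
  }, numeric(1))
  expect_gte(mean(purity >= 0.8), 0.7)
})

test_that("a planted rare type surfaces as dedicated rare-module metacells", {
  g <- generate_states(2, 800, 12000,
                       separation = 2, seed = 67)
  pr <- plant_rare_type(g$matrix, g$truth, 12 / 12000, module_size = 5,
                        enrichment = 50, seed = 5)
  cfg <- mc2_config(target_umis = 40000)
  sol <- run_mc2(pr$matrix, cfg, seed = 11)
  rare_mcs <- which(startsWith(sol$provenance, "rare"))
  expect_gte(length(rare_mcs), 1L)
  planted <- match(pr$truth$rare_modules[[1]]$cells, rownames(pr$matrix))
  in_rare <- sol$assignment[planted] %in% rare_mcs
  expect_gte(mean(in_rare), 0.8)
})
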