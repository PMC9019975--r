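test_that("MTX round trip preserves counts, names and orientation", {
  m <- tiny_umis(3, 4)
  d <- withr::local_tempdir()
  save_umi_matrix(m, d)
  m2 <- load_umi_matrix(d)
  expect_equal(as.matrix(m2), as.matrix(m))
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  # a 2-column genes.tsv dialect reads too
  d2 <- withr::local_tempdir()
  file.copy(file.path(d, "matrix.mtx"), file.path(d2, "matrix.mtx"))
  file.copy(file.path(d, "barcodes.tsv"), file.path(d2, "barcodes.tsv"))
  write.table(data.frame(colnames(m), colnames(m)),
              file.path(d2, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_equal(as.matrix(load_umi_matrix(d2)), as.matrix(m))
})

test_that("HDF5 (AnnData layout) round trip preserves the matrix", {
  m <- tiny_umis(5, 6, seed = 2)
  f <- file.path(withr::local_tempdir(), "x.h5ad")
  save_umi_matrix(m, f, format = "h5")
  m2 <- load_umi_matrix(f, format = "h5")
  expect_equal(as.matrix(m2), as.matrix(m))
  expect_identical(rownames(m2), rownames(m))
})

test_that("degenerate and non-integer inputs are rejected with clear errors", {
  expect_error(load_umi_matrix(withr::local_tempdir()), "none of")
  m <- tiny_umis()
  bad <- m
  bad@x[1] <- 1.5
  expect_error(validate_umi_matrix(bad), "non-integer")
  expect_error(umi_matrix(Matrix::sparseMatrix(i = 1, j = 1, x = 1,
                                               dims = c(1, 1))),
               "cell ids")
})

test_that("cell_sizes caps per-cell totals at twice the median and derives the size window", {
  cs <- cell_sizes(c(1000, 2000, 3000, 10000), target_umis = 160000)
  expect_equal(cs$u_capped, c(1000, 2000, 3000, 5000))
  expect_equal(cs$U_low, 80000)
  expect_equal(cs$U_high, 320000)
})

test_that("filter recipes remove planted violations exactly and are idempotent", {
  set.seed(4)
  n <- 1000
  m <- one_state_matrix(n, 300, depth = 2400, seed = 4)  # natural depths >= 1200
  # plant 50 low-depth cells by truncating their counts
  low <- sort(sample(n, 50))
  mt <- as.matrix(m)
  for (c_i in low) {
    row <- mt[c_i, ]
    keep <- sample(rep(seq_along(row), row), 500)
    mt[c_i, ] <- tabulate(keep, length(row))
  }
  m <- umi_matrix(mt)
  r <- filter_recipe(min_cell_umis = 800, exclude_mitochondrial = FALSE)
  res <- apply_filter_recipe(m, r)
  expect_equal(res$report$n_cells_removed, 50L)
  expect_setequal(res$report$removed_cells[[1]], rownames(m)[low])
  # idempotence: the second pass removes no cells and only genes that were
  # left without any count by the first pass's cell removal
  res2 <- apply_filter_recipe(res$matrix, r)
  expect_equal(res2$report$n_cells_removed, 0L)
  gone <- res2$report$removed_genes[[1]]
  expect_true(all(Matrix::colSums(res$matrix)[gone] == 0))
  kept <- setdiff(colnames(res$matrix), gone)
  expect_equal(as.matrix(res2$matrix), as.matrix(res$matrix[, kept]))
  # identity recipe
  rid <- filter_recipe(exclude_mitochondrial = FALSE)
  resid <- apply_filter_recipe(m, rid)
  expect_equal(dim(resid$matrix), dim(m) - c(0, sum(Matrix::colSums(m) == 0)))
  # removing every cell errors
  expect_error(apply_filter_recipe(m, filter_recipe(min_cell_umis = 1e7)),
               "every cell")
})

test_that("the excluded-UMI fraction uses the pre-removal denominator and mitochondrial prefix matching works", {
  mt <- matrix(0L, 4, 3, dimnames = list(paste0("c", 1:4),
                                         c("MT-CO1", "ACTB", "GAPDH")))
  mt[, "ACTB"] <- c(90L, 90L, 90L, 90L)
  mt[, "GAPDH"] <- c(5L, 5L, 5L, 5L)
  mt[, "MT-CO1"] <- c(5L, 30L, 5L, 5L)  # cell 2: 30/125 = 24% mito
  m <- umi_matrix(mt)
  r <- filter_recipe(exclude_mitochondrial = TRUE, max_excluded_fraction = 0.1)
  res <- apply_filter_recipe(m, r)
  expect_false("MT-CO1" %in% colnames(res$matrix))
  expect_setequal(res$report$removed_cells[[1]], "c2")
})

test_that("recipe YAML round trip and shipped presets hold their thresholds", {
  r <- filter_recipe(excluded_gene_names = c("A", "B"), min_cell_umis = 500,
                     max_cell_umis = 9000, max_excluded_fraction = 0.2)
  f <- file.path(withr::local_tempdir(), "recipe.yaml")
  write_filter_recipe(r, f)
  r2 <- read_filter_recipe(f)
  expect_equal(r2$excluded_gene_names, c("A", "B"))
  expect_equal(r2$min_cell_umis, 500)
  expect_equal(r2$max_excluded_fraction, 0.2)
  for (nm in c("pbmc", "hca_bm", "moca")) {
    p <- recipe_preset(nm)
    expect_s3_class(p, "filter_recipe")
    expect_true(p$exclude_mitochondrial)
  }
})

test_that("downsampling conserves the target exactly, never increases counts, and matches the hypergeometric expectation", {
  m <- tiny_umis(4, 6, seed = 5)
  tot <- Matrix::rowSums(m)
  target <- min(tot)  # at-target cell stays untouched
  ds <- downsample_cells(m, target, seed = 1)
  expect_true(all(Matrix::rowSums(ds) == pmin(tot, target)))
  expect_true(all(as.matrix(ds) <= as.matrix(m)))
  expect_equal(as.matrix(ds)[which.min(tot), ], as.matrix(m)[which.min(tot), ])
  # expectation: mean downsampled count ~ original * target / total
  counts <- c(40, 25, 15, 20)
  m1 <- umi_matrix(matrix(counts, 1, 4, dimnames = list("c1", paste0("g", 1:4))))
  acc <- matrix(0, 400, 4)
  for (s in seq_len(400)) acc[s, ] <- as.numeric(downsample_cells(m1, 50, seed = s))
  expect_equal(colMeans(acc), counts * 50 / 100, tolerance = 0.06)
  # determinism
  expect_identical(downsample_cells(m, target, seed = 9),
                   downsample_cells(m, target, seed = 9))
})
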