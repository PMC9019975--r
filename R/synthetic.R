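#' Synthetic multinomial scRNA-seq data with ground truth
#'
#' The generator emulates the idealized model under which metacells are
#' defined: every cell is a multinomial sample from the expression profile
#' of its (discrete) state at its own sequencing depth. It produces sparse
#' heavy-tailed profiles, log-normal depth variation, optional planted rare
#' cell types, and optional planted deviant (outlier) cells — each recorded
#' in a `ground_truth` object so recovery can be scored exactly.
#'
#' @param n_states number of discrete cell states.
#' @param n_genes number of genes.
#' @param n_cells number of cells.
#' @param depth_distribution a list as produced by [depth_lognormal()].
#' @param separation fold-change of each state's specific genes over the
#'   shared backbone (pairwise state divergence dial).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param profile_shape gamma shape of the Dirichlet-like profile draw;
#'   small values give the heavy-tailed, sparse profiles typical of UMI
#'   data.
#' @param n_specific number of state-specific genes per state.
#' @param n_sporadic number of very-low-abundance background genes (these
#'   exercise the rare-gene abundance filter: rarely seen, never abundant).
#' @param n_micro number of micro-populations: tiny cell subsets (about
#'   0.02% of cells each) abundantly expressing one dedicated marker gene.
#'   Real UMI data always carries such sparse rare behaviors, and the
#'   second-order correlation step needs them as context; without them a
#'   lone planted module is the entire rare-gene universe and `cor(r)`
#'   degenerates.
#' @param micro_umis mean UMIs of a micro marker in its cells.
#' @return a list with `matrix` (cells x genes UMI matrix) and `truth`
#'   (a `ground_truth` object: per-cell `state`, `profiles` (states x
#'   genes), `specific_genes`, `rare_modules`, `deviants`, `depths`).
#' @export
generate_states <- function(n_states, n_genes, n_cells,
                            depth_distribution = depth_lognormal(),
                            separation = 4, seed = 1L,
                            profile_shape = 0.03,
                            n_specific = max(5L, round(0.01 * n_genes)),
                            n_sporadic = min(40L, n_genes %/% 10),
                            n_micro = min(20L, n_genes %/% 20),
                            micro_umis = 12) {
  assert_that(n_states >= 1 && n_genes >= 10 && n_cells >= 1,
              "degenerate generator request")
  set.seed(derive_seed(seed, "profiles"))
  base <- stats::rgamma(n_genes, shape = profile_shape)
  base <- base / sum(base)
  ord <- order(base, decreasing = TRUE)
  # sporadic genes: tiny but nonzero probability in every state, tuned so
  # roughly 5e-4 of cells show >= 1 UMI (rare in cells, never abundant)
  sporadic <- ord[seq.int(n_genes - n_sporadic + 1, length.out = n_sporadic)]
  if (n_sporadic > 0) base[sporadic] <- 5e-4 / depth_distribution$median_umis
  # micro markers: reserved for post-hoc injection into micro-populations
  micro <- ord[seq.int(n_genes - n_sporadic - n_micro + 1,
                       length.out = n_micro)]
  if (n_micro > 0) base[micro] <- 0
  base <- base / sum(base)
  # state-specific genes: disjoint mid-expression blocks, boosted
  # `separation`-fold in their own state
  spec_pool <- ord[seq.int(11, length.out = min(n_states * n_specific,
                                                n_genes - 10 - n_sporadic))]
  specific <- split(spec_pool,
                    rep(seq_len(n_states), each = n_specific,
                        length.out = length(spec_pool)))
  profiles <- matrix(rep(base, n_states), nrow = n_states, byrow = TRUE)
  if (separation != 1) {
    for (s in seq_len(n_states)) {
      gs <- specific[[as.character(s)]] %||% specific[[s]]
      profiles[s, gs] <- profiles[s, gs] * separation
      profiles[s, ] <- profiles[s, ] / sum(profiles[s, ])
    }
  }
  set.seed(derive_seed(seed, "cells"))
  state <- sample(rep_len(seq_len(n_states), n_cells))
  depths <- draw_depths(depth_distribution, n_cells)
  trip_i <- vector("list", n_states)
  trip_j <- vector("list", n_states)
  trip_x <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    idx <- which(state == s)
    set.seed(derive_seed(seed, "counts", s))
    tr <- sample_multinomial_counts(depths[idx], profiles[s, ])
    trip_i[[s]] <- idx[tr$i]
    trip_j[[s]] <- tr$j
    trip_x[[s]] <- tr$x
  }
  # micro-populations: inject the dedicated marker into a tiny cell subset,
  # stealing the injected UMIs from the cell's most abundant gene so the
  # drawn depth is preserved exactly
  micro_cells_each <- max(8L, round(2e-4 * n_cells))
  if (n_micro > 0) {
    set.seed(derive_seed(seed, "micro"))
    ti <- unlist(trip_i); tj <- unlist(trip_j); tx <- unlist(trip_x)
    ord_t <- order(ti)
    ti_s <- as.double(ti[ord_t])
    mi <- mj <- mx <- integer(0)
    for (k in seq_len(n_micro)) {
      cells_k <- sample.int(n_cells, micro_cells_each)
      add <- stats::rpois(micro_cells_each, micro_umis)
      keep <- add > 0
      cells_k <- cells_k[keep]; add <- add[keep]
      if (!length(cells_k)) next
      lo <- findInterval(cells_k - 0.5, ti_s) + 1L
      hi <- findInterval(cells_k + 0.5, ti_s)
      for (ci in seq_along(cells_k)) {
        if (hi[ci] < lo[ci]) next
        sel <- ord_t[lo[ci]:hi[ci]]
        big <- sel[which.max(tx[sel])]
        take <- min(add[ci], tx[big] - 1L)
        tx[big] <- tx[big] - take
        mi <- c(mi, cells_k[ci]); mj <- c(mj, micro[k]); mx <- c(mx, take)
      }
    }
    trip_i <- list(c(ti, mi)); trip_j <- list(c(tj, mj))
    trip_x <- list(c(tx, mx))
  }
  m <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n_cells, n_genes),
    dimnames = list(sprintf("cell_%06d", seq_len(n_cells)),
                    sprintf("gene_%05d", seq_len(n_genes))))
  m <- Matrix::drop0(m)
  truth <- structure(
    list(state = state,
         profiles = profiles,
         specific_genes = lapply(specific, function(g) colnames(m)[g]),
         sporadic_genes = colnames(m)[sporadic],
         micro_genes = colnames(m)[micro],
         rare_modules = list(),
         deviants = tibble::tibble(cell = character(), gene = character(),
                                   fold = numeric()),
         depths = depths,
         seed = seed),
    class = "ground_truth")
  list(matrix = m, truth = truth)
}

#' @rdname generate_states
#' @param median_umis,sdlog,min_umis,max_umis log-normal depth parameters:
#'   median depth, standard deviation in log space, and truncation bounds
#'   (defaults mimic typical filtered 10x libraries).
#' @export
depth_lognormal <- function(median_umis = 2000, sdlog = 0.4,
                            min_umis = 500, max_umis = 20000) {
  list(median_umis = median_umis, sdlog = sdlog,
       min_umis = min_umis, max_umis = max_umis)
}

draw_depths <- function(d, n) {
  x <- stats::rlnorm(n, meanlog = log(d$median_umis), sdlog = d$sdlog)
  as.integer(round(clamp(x, d$min_umis, d$max_umis)))
}

# Multinomial counts for many cells sharing one profile, via the sequential
# conditional-binomial decomposition (gene-major, in C). Returns triplets
# (i = cell index within `depths`, j = gene, x = count).
sample_multinomial_counts <- function(depths, prob) {
  prob <- as.numeric(prob)
  # genes whose expected total count over the whole draw is < 1e-3 are
  # numerically indistinguishable from absent; dropping them keeps the
  # gene-major sampler loop proportional to the genes that can appear
  prob[prob * sum(as.numeric(depths)) < 1e-3] <- 0
  cpp_multinomial_counts(as.integer(depths), prob)
}

#' Plant a rare cell type expressing a dedicated gene module
#'
#' Selects `round(frequency * n_cells)` cells and redraws their counts (at
#' their original depths) from a rare-state profile in which `module_size`
#' dedicated genes each carry `enrichment` times the uniform per-gene
#' probability share (`enrichment / n_genes`); the dedicated genes are taken
#' from genes with (essentially) zero baseline expression, so the planted
#' module is both rare and abundant in its cells — the regime the
#' rare-gene-module detector targets.
#'
#' @param m,truth a matrix/truth pair from [generate_states()].
#' @param frequency fraction of all cells to convert (0 for identity).
#' @param module_size number of dedicated module genes.
#' @param enrichment fold over the uniform per-gene probability share.
#' @param seed integer seed.
#' @return an updated `list(matrix, truth)`; the planted module is appended
#'   to `truth$rare_modules`.
#' @export
plant_rare_type <- function(m, truth, frequency, module_size = 5,
                            enrichment = 50, seed = 1L) {
  n_cells <- nrow(m)
  n_genes <- ncol(m)
  n_plant <- round(frequency * n_cells)
  if (n_plant == 0) return(list(matrix = m, truth = truth))
  set.seed(derive_seed(seed, "plant_rare"))
  used <- c(unlist(lapply(truth$rare_modules, `[[`, "genes")),
            truth$sporadic_genes, truth$micro_genes)
  base_tot <- colSums(truth$profiles)
  candidates <- setdiff(order(base_tot), match(used, colnames(m)))
  module <- sort(utils::head(candidates, module_size))
  planted <- sort(sample.int(n_cells, n_plant))
  prof <- truth$profiles[1, ]
  prof[module] <- 0
  p_mod <- enrichment / n_genes
  prof <- prof / sum(prof) * (1 - p_mod * module_size)
  prof[module] <- p_mod
  tr <- sample_multinomial_counts(truth$depths[planted], prof)
  sm <- Matrix::summary(m)
  keep <- !(sm$i %in% planted)
  m2 <- Matrix::sparseMatrix(
    i = c(sm$i[keep], planted[tr$i]),
    j = c(sm$j[keep], tr$j),
    x = c(sm$x[keep], tr$x),
    dims = dim(m), dimnames = dimnames(m))
  truth$state[planted] <- max(truth$state) + 1L
  truth$rare_modules <- c(
    truth$rare_modules,
    list(list(genes = colnames(m)[module], cells = rownames(m)[planted],
              frequency = frequency, enrichment = enrichment)))
  list(matrix = methods::as(m2, "CsparseMatrix"), truth = truth)
}

#' Plant deviant (outlier) cells
#'
#' Each chosen cell gets one randomly chosen expressed gene's count
#' multiplied by `fold`; the surplus UMIs are compensated by downsampling
#' the cell's other genes, so the cell's total depth is preserved exactly.
#'
#' @inheritParams plant_rare_type
#' @param n_deviant number of cells to corrupt.
#' @param fold linear over-expression factor (1 for identity).
#' @export
plant_deviant_cells <- function(m, truth, n_deviant, fold, seed = 1L) {
  if (n_deviant == 0 || fold == 1) return(list(matrix = m, truth = truth))
  set.seed(derive_seed(seed, "plant_dev"))
  cells <- sort(sample.int(nrow(m), n_deviant))
  m <- methods::as(m, "CsparseMatrix")
  recs <- vector("list", n_deviant)
  for (k in seq_along(cells)) {
    c_i <- cells[k]
    row <- m[c_i, ]
    nz <- which(row > 0)
    depth0 <- sum(row)
    # prefer moderately expressed genes whose boost fits within the depth,
    # so the planted fold is unambiguous
    cand <- nz[row[nz] >= 2 & row[nz] * fold <= 0.6 * depth0]
    if (!length(cand)) cand <- nz[row[nz] >= 2]
    if (!length(cand)) cand <- nz
    g <- cand[sample.int(length(cand), 1)]
    depth <- sum(row)
    boosted <- min(round(row[g] * fold), depth)
    rest <- row
    rest[g] <- 0
    rest_target <- depth - boosted
    if (sum(rest) > rest_target) {
      rest_m <- Matrix::sparseMatrix(i = rep(1L, sum(rest > 0)),
                                     j = which(rest > 0),
                                     x = rest[rest > 0],
                                     dims = c(1L, length(rest)))
      rest_m <- methods::as(Matrix::t(rest_m), "CsparseMatrix")
      rest <- as.numeric(cpp_downsample_csc(rest_m@p, rest_m@x, rest_target))
      new_row <- numeric(length(row))
      new_row[rest_m@i + 1L] <- rest
    } else {
      new_row <- rest
    }
    new_row[g] <- boosted
    m[c_i, ] <- new_row
    recs[[k]] <- tibble::tibble(cell = rownames(m)[c_i],
                                gene = colnames(m)[g], fold = fold)
  }
  truth$deviants <- rbind(truth$deviants, do.call(rbind, recs))
  list(matrix = Matrix::drop0(m), truth = truth)
}

#' Serialize ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
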