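# Missing-aware distances, neighbor graphs and drop-out imputation.

test_that("scaled Manhattan distance follows the pairwise-complete formula", {
  G <- rbind(c(0L, 1L, 2L), c(2L, 1L, 0L))
  d <- manhattan_distances(gm_from_matrix(G), min_overlap = 1)
  expect_equal(d$d[1, 2], 4)           # |0-2| + 0 + |2-0|
  expect_equal(diag(d$d), c(0, 0), ignore_attr = TRUE)

  G2 <- rbind(c(0L, 1L, NA), c(1L, 1L, 0L))
  d2 <- manhattan_distances(gm_from_matrix(G2), min_overlap = 1)
  expect_equal(d2$d[1, 2], 1.5)        # raw 1 over overlap 2, scaled to 3
  expect_equal(d2$overlap[1, 2], 2)

  same <- manhattan_distances(gm_from_matrix(rbind(c(1L, 2L, 0L),
                                                   c(1L, 2L, 0L))),
                              min_overlap = 1)
  expect_equal(same$d[1, 2], 0)
})

test_that("pairs below the overlap floor are incomparable, matrix symmetric", {
  set.seed(2)
  G <- matrix(sample(c(0:2, NA), 100, replace = TRUE,
                     prob = c(.2, .2, .2, .4)), 10, 10)
  d <- manhattan_distances(gm_from_matrix(G), min_overlap = 5)
  expect_true(isSymmetric(d$d))
  expect_equal(diag(d$d), rep(0, 10), ignore_attr = TRUE)
  low <- d$overlap < 5; diag(low) <- FALSE
  expect_true(all(is.na(d$d[low])))
  expect_true(all(d$d[!is.na(d$d)] >= 0))
})

test_that("neighbor graphs respect distance quantile, annotation and planted clones", {
  G <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L))
  d <- manhattan_distances(gm_from_matrix(G), min_overlap = 1)
  g <- find_neighbors(d, dist_quantile = 0.5)
  expect_equal(g$neighbors[[1]], rownames(G)[2] %||% "c02")
  expect_equal(g$neighbors[[2]], "c01")

  ann <- data.frame(cell_id = c("c01", "c02"), cell_type = c("T", "B"))
  g2 <- find_neighbors(d, annotations = ann, same_type = TRUE)
  expect_length(g2$neighbors[[1]], 0)

  # 5-cell, 2-clone fixture: neighbor sets = clone co-membership
  G5 <- rbind(matrix(0L, 3, 6), matrix(1L, 2, 6))
  rownames(G5) <- paste0("c", 1:5)
  d5 <- manhattan_distances(gm_from_matrix(G5), min_overlap = 1)
  g5 <- find_neighbors(d5, dist_quantile = 0.2)
  expect_setequal(g5$neighbors[["c1"]], c("c2", "c3"))
  expect_setequal(g5$neighbors[["c4"]], "c5")
})

test_that("imputation fills only missing entries by weighted majority", {
  G <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(NA, 1L))
  rownames(G) <- paste0("c", 1:4)
  gm <- gm_from_matrix(G)
  d <- manhattan_distances(gm, min_overlap = 1)
  g <- find_neighbors(d, dist_quantile = 1)
  out <- impute_dropouts(gm, g, min_votes = 3)
  expect_identical(unname(out$genotype["c4", 1]), 1L)
  expect_identical(out$genotype[1:3, ], gm$genotype[1:3, ])

  # no missing entries: identity
  full <- gm_from_matrix(matrix(1L, 3, 4))
  df <- manhattan_distances(full, min_overlap = 1)
  gf <- find_neighbors(df, dist_quantile = 1)
  expect_identical(impute_dropouts(full, gf)$genotype, full$genotype)
})

test_that("tied votes leave the entry missing", {
  # two neighbors at genotype 0, two at genotype 1, equal weights
  G <- rbind(c(0L, 0L, 0L, 0L, NA), c(0L, 0L, 0L, 0L, 0L),
             c(0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 1L),
             c(0L, 0L, 0L, 0L, 1L))
  rownames(G) <- paste0("c", 1:5)
  gm <- gm_from_matrix(G)
  d <- manhattan_distances(gm, min_overlap = 1)
  g <- find_neighbors(d, dist_quantile = 1)
  out <- impute_dropouts(gm, g, min_votes = 3)
  expect_true(is.na(out$genotype["c1", 5]))
})

test_that("imputation is idempotent on observed entries", {
  set.seed(13)
  sim <- simulate_clonal_population(seed = 3)
  gm <- build_genotype_matrix(sim$counts[is_editing == FALSE], min_sites = 5)
  d <- manhattan_distances(gm, min_overlap = 3)
  g <- find_neighbors(d, dist_quantile = 0.15)
  once <- impute_dropouts(gm, g, min_votes = 3)
  twice <- impute_dropouts(once, g, min_votes = 3)
  obs <- !is.na(gm$genotype)
  expect_identical(once$genotype[obs], gm$genotype[obs])
  expect_identical(twice$genotype[obs], gm$genotype[obs])
})

test_that("imputation raises the true-label silhouette on 3-clone data", {
  sim <- simulate_clonal_population(
    params = list(dropout = 0.3, depth_mean = 20), seed = 17)
  gm <- build_genotype_matrix(sim$counts[is_editing == FALSE], min_sites = 5)
  truth <- sim$truth$clone[gm$cells]
  d0 <- manhattan_distances(gm, min_overlap = 3)
  sil0 <- mean(cluster::silhouette(as.integer(truth),
                                   dmatrix = clonescope:::.complete_dist(d0$d))[, 3])
  g <- find_neighbors(d0, dist_quantile = 0.15)
  sm <- impute_dropouts(gm, g, min_votes = 3)
  d1 <- manhattan_distances(sm, min_overlap = 3)
  sil1 <- mean(cluster::silhouette(as.integer(truth),
                                   dmatrix = clonescope:::.complete_dist(d1$d))[, 3])
  expect_gte(sil1, sil0)
})
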