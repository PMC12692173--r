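# Clustering metrics, hierarchical clone calling, random-forest mutation
# scoring and refinement.

test_that("pair-count indices match exhaustive oracles on all partitions of 7 items", {
  ref <- c(1, 1, 2, 2, 3, 3, 3)
  parts <- all_partitions(7)
  for (lab in parts) {
    o <- pair_count_oracle(lab, ref)
    expect_equal(adjusted_rand_index(lab, ref), o$ari, tolerance = 1e-12)
    expect_equal(fowlkes_mallows_index(lab, ref), o$fm, tolerance = 1e-12)
    expect_equal(normalized_mutual_information(lab, ref), nmi_oracle(lab, ref),
                 tolerance = 1e-12)
  }
})

test_that("external indices behave on identical, permuted and known labelings", {
  ref <- c("a", "a", "b", "b", "c")
  expect_equal(adjusted_rand_index(ref, ref), 1)
  expect_equal(normalized_mutual_information(ref, ref), 1)
  expect_equal(fowlkes_mallows_index(ref, ref), 1)
  perm <- c("x", "x", "y", "y", "z")       # renamed labels
  expect_equal(adjusted_rand_index(perm, ref), 1)
  # contingency [[2,0],[1,1]]: hand-evaluated ARI from the expectation formula
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
})

test_that("internal indices match independent loop-based implementations", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 4), 10))
  lab <- rep(1:2, each = 10)
  # Calinski-Harabasz by direct sums of squares
  grand <- colMeans(x)
  B <- W <- 0
  for (l in 1:2) {
    xi <- x[lab == l, ]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    W <- W + sum(t(t(xi) - ci)^2)
  }
  ch_oracle <- (B / 1) / (W / 18)
  expect_equal(calinski_harabasz(x, lab), ch_oracle, tolerance = 1e-12)
  # Davies-Bouldin by definition
  c1 <- colMeans(x[1:10, ]); c2 <- colMeans(x[11:20, ])
  s1 <- mean(sqrt(rowSums(t(t(x[1:10, ]) - c1)^2)))
  s2 <- mean(sqrt(rowSums(t(t(x[11:20, ]) - c2)^2)))
  db_oracle <- (s1 + s2) / sqrt(sum((c1 - c2)^2))
  expect_equal(davies_bouldin(x, lab), db_oracle, tolerance = 1e-12)
  ev <- evaluate_clustering(lab, reference = lab, x = x,
                            distances = as.matrix(dist(x)))
  expect_equal(ev$adjusted_rand, 1)
  expect_true(ev$silhouette > 0.5)
})

test_that("hierarchical clustering recovers planted blocks and picks k by silhouette", {
  set.seed(6)
  G <- rbind(matrix(0L, 8, 20), matrix(1L, 8, 20))
  G[9:16, 1:10] <- 2L
  gm <- gm_from_matrix(G + matrix(rbinom(320, 1, 0.02), 16, 20))
  d <- manhattan_distances(gm, min_overlap = 1)
  cand <- hierarchical_clones(d, k_range = 2:6)
  expect_equal(cand$chosen_k, 2)
  expect_equal(adjusted_rand_index(cand$labels, rep(1:2, each = 8)), 1)

  # three planted clones
  G3 <- rbind(matrix(0L, 6, 30), matrix(1L, 6, 30), matrix(2L, 6, 30))
  d3 <- manhattan_distances(gm_from_matrix(G3), min_overlap = 1)
  cand3 <- hierarchical_clones(d3, k_range = 2:6)
  expect_equal(cand3$chosen_k, 3)

  # k_range pinned to 2 gives exactly 2 labels
  two <- hierarchical_clones(d3, k_range = c(2, 2))
  expect_equal(length(unique(two$labels)), 2)

  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_error(hierarchical_clones(flat, 2:3), "equal")
})

test_that("random forest ranks a perfectly partitioning mutation highest", {
  set.seed(31)
  n <- 40
  lab <- rep(1:2, each = n / 2)
  G <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10)
  G[, 4] <- ifelse(lab == 1, 0L, 2L)   # clone-defining site
  G[, 7] <- 1L                          # constant site
  colnames(G) <- sprintf("s%02d", 1:10)
  a <- rf_assess_mutations(G, lab, n_trees = 300, seed = 2)
  expect_equal(which.max(a$scores$gini), 4L)
  expect_lt(a$scores$gini[7], 1e-8)
  expect_equal(sum(a$scores$gini), 1, tolerance = 1e-9)
  # determinism under a fixed seed
  b <- rf_assess_mutations(G, lab, n_trees = 300, seed = 2)
  expect_identical(a$scores, b$scores)
  expect_identical(a$cv_accuracy, b$cv_accuracy)
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(77)
  n <- 40
  G <- matrix(sample(0:2, n * 12, replace = TRUE), n, 12)
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    lab <- sample(rep(1:2, each = n / 2))
    rf_assess_mutations(G, lab, n_trees = 100, seed = s)$cv_accuracy
  }, numeric(1))
  # binomial chance level 0.5; mean over 20 shuffles within 2 SE
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 0.05)
})

test_that("refinement removes label-shuffled noise sites and never grows", {
  set.seed(55)
  n <- 30
  lab_true <- rep(1:3, each = 10)
  clean <- outer(lab_true, sort(rep(1:3, length.out = 40)), ">=") * 1L
  noise <- matrix(sample(0:1, n * 10, replace = TRUE), n, 10)
  G <- cbind(clean, noise)
  colnames(G) <- c(sprintf("clean%02d", 1:40), sprintf("noise%02d", 1:10))
  rownames(G) <- sprintf("c%02d", 1:n)
  gm <- gm_from_matrix(G)
  d <- manhattan_distances(gm, min_overlap = 1)
  cand <- hierarchical_clones(d, k_range = 2:5)
  fin <- refine_clones(gm, cand, gini_quantile = 0.5, k_range = 2:5,
                       n_trees = 300, seed = 3)
  noise_kept <- grep("noise", fin$retained_sites, value = TRUE)
  expect_lte(length(noise_kept), 1)    # >= 90% of the 10 noise sites removed
  expect_lte(length(fin$retained_sites), ncol(G))
  expect_equal(adjusted_rand_index(fin$labels, lab_true), 1)
})

test_that("variant-cell map ordering produces the clonal staircase", {
  # 2-clone nested sets on a 4x6 toy: sites 1-2 shared, 3-4 clone-2 only,
  # 5 sparse, 6 rare
  G <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 0L, 0L, 1L, 0L),
             c(1L, 1L, 1L, 1L, 0L, 0L),
             c(1L, 1L, 1L, 1L, 1L, 1L))
  rownames(G) <- paste0("c", 1:4)
  colnames(G) <- paste0("s", 1:6)
  gm <- gm_from_matrix(G)
  asn <- structure(list(labels = setNames(c(1L, 1L, 2L, 2L), rownames(G))),
                   class = "clonal_assignment")
  ord <- order_variant_cell_map(gm, asn)
  expect_equal(ord$cell_order, c("c1", "c2", "c3", "c4"))
  # shared sites first, then clone-2-specific, then sparse ones
  expect_equal(ord$site_order[1:2], c("s1", "s2"))
  expect_true(all(which(ord$site_order %in% c("s3", "s4")) <
                    which(ord$site_order %in% c("s5", "s6"))))
  expect_error(order_variant_cell_map(gm, structure(list(labels = NULL),
                                                    class = "clonal_assignment")),
               "empty")
})

test_that("clone tree export yields parseable Newick", {
  G <- rbind(matrix(0L, 5, 12), matrix(1L, 5, 12), matrix(2L, 5, 12))
  d <- manhattan_distances(gm_from_matrix(G), min_overlap = 1)
  cand <- hierarchical_clones(d, k_range = 2:4)
  nwk <- clone_newick(cand)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label),
               sort(paste0("clone_", unique(cand$labels))))
})
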