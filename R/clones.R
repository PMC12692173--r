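## Clonal clustering: UPGMA on genotype distances, silhouette-guided choice
## of clone count, random-forest scoring of clone-defining mutations, and
## iterative refinement to a low-complexity clonal structure.

# replace incomparable (NA) distances by the largest finite distance so the
# agglomeration is defined; incomparable pairs are by construction the pairs
# with least shared evidence.
.complete_dist <- function(D) {
  mx <- max(D, na.rm = TRUE)
  D[is.na(D)] <- mx
  diag(D) <- 0
  D
}

.mean_silhouette <- function(D, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Hierarchical clone candidates over a range of k
#'
#' Builds one average-linkage (UPGMA) tree on the cell distance matrix and
#' cuts it at every k in `k_range`. The chosen k maximizes the penalized
#' mean silhouette `sil(k) - complexity_penalty * (k - 2)`; ties go to the
#' smaller k (lower-complexity clonal structure).
#'
#' @param distances a `cell_distances` object or symmetric matrix.
#' @param k_range integer candidate clone counts, within `[2, n_cells - 1]`.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param complexity_penalty silhouette penalty per extra clone.
#' @return list of class `clonal_assignment`: `labels` (named integer vector
#'   for `chosen_k`), `chosen_k`, `by_k` (labels per candidate k),
#'   `silhouette` (per k), `hclust` (the tree).
#' @export
hierarchical_clones <- function(distances, k_range = 2:10,
                                linkage = "average",
                                complexity_penalty = 0) {
  D <- if (inherits(distances, "cell_distances")) distances$d else as.matrix(distances)
  v <- D[upper.tri(D)]
  v <- v[!is.na(v)]
  if (length(v) && diff(range(v)) < 1e-12) {
    stop("all pairwise distances are equal: no clonal structure to cluster")
  }
  D <- .complete_dist(D)
  n <- nrow(D)
  k_range <- sort(unique(pmin(pmax(as.integer(k_range), 2L), n - 1L)))
  hc <- hclust(as.dist(D), method = linkage)
  by_k <- lapply(k_range, function(k) cutree(hc, k = k))
  names(by_k) <- k_range
  sil <- vapply(by_k, function(l) .mean_silhouette(D, l), numeric(1))
  score <- sil - complexity_penalty * (k_range - 2)
  best <- k_range[which.max(score)]   # which.max takes the first (smallest k) tie
  structure(list(labels = by_k[[as.character(best)]],
                 chosen_k = best, by_k = by_k,
                 silhouette = setNames(sil, k_range),
                 hclust = hc),
            class = "clonal_assignment")
}

#' @export
print.clonal_assignment <- function(x, ...) {
  cat("clonal_assignment: k =", x$chosen_k, "| sizes:",
      paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

## ---- clustering evaluation metrics (textbook definitions) ----------------

.pair_counts <- function(labels, reference) {
  ct <- table(labels, reference)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  list(ct = ct, n = n, TP = sum_ij, PA = sum_a, PB = sum_b,
       total = choose(n, 2))
}

#' Adjusted Rand index
#' @param labels,reference two labelings of the same items.
#' @return ARI (1 for identical partitions; ~0 at chance).
#' @export
adjusted_rand_index <- function(labels, reference) {
  p <- .pair_counts(labels, reference)
  expected <- p$PA * p$PB / p$total
  maxi <- (p$PA + p$PB) / 2
  if (maxi == expected) return(ifelse(p$TP == expected, 1, 0))
  (p$TP - expected) / (maxi - expected)
}

#' Fowlkes-Mallows index
#' @inheritParams adjusted_rand_index
#' @return FM in `[0, 1]`.
#' @export
fowlkes_mallows_index <- function(labels, reference) {
  p <- .pair_counts(labels, reference)
  if (p$PA == 0 || p$PB == 0) return(0)
  p$TP / sqrt(p$PA * p$PB)
}

#' Normalized mutual information
#' @inheritParams adjusted_rand_index
#' @return NMI in `[0, 1]` (sqrt normalization).
#' @export
normalized_mutual_information <- function(labels, reference) {
  ct <- table(labels, reference)
  n <- sum(ct)
  pij <- ct / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hu <- h(pi); hv <- h(pj)
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi / sqrt(hu * hv)
}

#' Calinski-Harabasz index
#' @param x numeric feature matrix (rows = items).
#' @param labels cluster labels.
#' @return CH statistic (higher = tighter, better-separated clusters).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  k <- nlevels(labels); n <- nrow(x)
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (lev in levels(labels)) {
    xi <- x[labels == lev, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(xi, 2, ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#' @inheritParams calinski_harabasz
#' @return DB statistic (lower is better).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  k <- nlevels(labels)
  if (k < 2) return(NA_real_)
  cents <- t(vapply(levels(labels),
                    function(l) colMeans(x[labels == l, , drop = FALSE]),
                    numeric(ncol(x))))
  s <- vapply(seq_len(k), function(i) {
    xi <- x[labels == levels(labels)[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cents[i, ])^2)))
  }, numeric(1))
  db <- 0
  for (i in seq_len(k)) {
    r <- vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cents[i, ] - cents[j, ])^2))
    }, numeric(1))
    db <- db + max(r)
  }
  db / k
}

#' Evaluate a clustering against a reference labeling
#'
#' Computes the internal (silhouette, Calinski-Harabasz, Davies-Bouldin)
#' and external (adjusted Rand, Fowlkes-Mallows, normalized mutual
#' information) indices by their standard definitions.
#'
#' @param labels cluster labels.
#' @param reference reference labels (e.g. sample origin or ground truth);
#'   `NULL` skips the external indices.
#' @param x optional feature matrix for CH/DB (e.g. the genotype matrix with
#'   missing entries as 0).
#' @param distances optional `cell_distances`/matrix for the silhouette.
#' @return named list of metric values.
#' @export
evaluate_clustering <- function(labels, reference = NULL, x = NULL,
                                distances = NULL) {
  out <- list()
  if (!is.null(distances)) {
    D <- if (inherits(distances, "cell_distances")) distances$d else as.matrix(distances)
    out$silhouette <- .mean_silhouette(.complete_dist(D), labels)
  }
  if (!is.null(x)) {
    out$calinski_harabasz <- calinski_harabasz(x, labels)
    out$davies_bouldin <- davies_bouldin(x, labels)
  }
  if (!is.null(reference)) {
    stopifnot(length(labels) == length(reference))
    out$adjusted_rand <- adjusted_rand_index(labels, reference)
    out$fowlkes_mallows <- fowlkes_mallows_index(labels, reference)
    out$nmi <- normalized_mutual_information(labels, reference)
  }
  out
}

## ---- random-forest mutation assessment -----------------------------------

# genotype matrix -> RF feature frame; missing coded as -1 (its own level of
# evidence: absence of expression is itself informative of clone membership)
.rf_features <- function(G) {
  X <- G
  X[is.na(X)] <- -1
  as.data.frame(X)
}

#' Score mutations against clone labels with a random forest
#'
#' Trains a random forest to predict clone labels from genotypes and reports
#' per-mutation Gini importance (normalized to sum 1) and permutation
#' ("accuracy") importance, plus stratified cross-validated accuracy per
#' clone. Classes smaller than `cv_folds` are merged into their nearest
#' clone (by centroid distance) for cross-validation only.
#'
#' @param gm a `genotype_matrix` or numeric matrix (cells x mutations).
#' @param labels clone labels, one per cell.
#' @param n_trees forest size.
#' @param seed RNG seed (forest and folds are deterministic given it).
#' @param cv_folds number of stratified folds.
#' @return list with `scores` (data.table: site, gini, accuracy),
#'   `cv_accuracy` (overall), `cv_by_class`, and the fitted `forest`.
#' @export
rf_assess_mutations <- function(gm, labels, n_trees = 500, seed = 1,
                                cv_folds = 5) {
  G <- if (inherits(gm, "genotype_matrix")) gm$genotype else as.matrix(gm)
  stopifnot(nrow(G) == length(labels))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 clone labels")
  X <- .rf_features(G)
  colnames(X) <- paste0("m", seq_len(ncol(X)))   # syntactic names for RF
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  gini <- imp[, "MeanDecreaseGini"]
  gini <- if (sum(gini) > 0) gini / sum(gini) else gini
  acc <- imp[, "MeanDecreaseAccuracy"]

  # stratified CV; tiny classes merged into nearest clone for CV only
  y_cv <- y
  small <- names(which(table(y) < cv_folds))
  if (length(small)) {
    Xn <- as.matrix(X)
    cents <- do.call(rbind, lapply(levels(y), function(l)
      colMeans(Xn[y == l, , drop = FALSE])))
    rownames(cents) <- levels(y)
    for (lev in small) {
      others <- setdiff(levels(y), small)
      if (!length(others)) break
      dd <- vapply(others, function(o) sum((cents[lev, ] - cents[o, ])^2),
                   numeric(1))
      y_cv[y_cv == lev] <- others[which.min(dd)]
      .cs_log("class ", lev, " merged into ", others[which.min(dd)],
              " for cross-validation")
    }
    y_cv <- droplevels(y_cv)
  }
  set.seed(seed + 1L)
  fold <- .stratified_folds(y_cv, cv_folds)
  pred <- factor(rep(NA_character_, length(y_cv)), levels = levels(y_cv))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    if (length(unique(y_cv[tr])) < 2) next
    m <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = y_cv[tr],
                                    ntree = max(100, n_trees %/% 5))
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  ok <- !is.na(pred)
  cv_acc <- mean(pred[ok] == y_cv[ok])
  by_class <- vapply(levels(y_cv), function(l) {
    sel <- ok & y_cv == l
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == l)
  }, numeric(1))

  list(scores = data.table(site = colnames(G), gini = unname(gini),
                           accuracy = unname(acc)),
       cv_accuracy = cv_acc, cv_by_class = by_class, forest = rf)
}

# a site is clone-consistent when every clone is cleanly mutated (nonzero
# prevalence >= hi) or cleanly wild-type (<= lo), with at least one mutated
# clone: its genotype maps onto one branch of the clone structure rather
# than scattering across clones.
.clone_consistent <- function(G, labels, hi = 0.5, lo = 0.2) {
  y <- factor(labels)
  prev <- vapply(levels(y), function(l) {
    colMeans(G[y == l, , drop = FALSE] > 0, na.rm = TRUE)
  }, numeric(ncol(G)))
  if (is.null(dim(prev))) prev <- matrix(prev, ncol = nlevels(y))
  prev[is.na(prev)] <- 0
  apply(prev, 1, function(p) all(p >= hi | p <= lo) && any(p >= hi))
}

#' Refine a clonal assignment to clone-defining mutations
#'
#' Iteratively retains mutations whose Gini importance exceeds the
#' `gini_quantile` cutoff and whose prevalence pattern is consistent with
#' the clone structure, re-clusters the cells on the retained sites, and
#' stops at a fixed point (labels unchanged) or after `max_rounds`. The
#' retained set never grows between rounds. An empty retained set falls
#' back to the candidate assignment with a warning.
#'
#' @param gm a `genotype_matrix`.
#' @param candidate a `clonal_assignment` from [hierarchical_clones()].
#' @param gini_quantile quantile of Gini importance below which mutations
#'   are discarded.
#' @param complexity_penalty passed to the re-clustering step.
#' @param k_range candidate clone counts for re-clustering.
#' @param n_trees,seed,cv_folds passed to [rf_assess_mutations()].
#' @param max_rounds refinement iteration cap.
#' @param min_overlap passed to [manhattan_distances()].
#' @return list of class `clonal_assignment` with additional elements
#'   `retained_sites`, `scores`, `cv_accuracy`, `rounds`.
#' @export
refine_clones <- function(gm, candidate, gini_quantile = 0.75,
                          complexity_penalty = 0, k_range = 2:10,
                          n_trees = 500, seed = 1, cv_folds = 5,
                          max_rounds = 5, min_overlap = 5) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(candidate, "clonal_assignment"))
  labels <- candidate$labels
  retained <- colnames(gm$genotype)
  assess <- NULL
  final <- candidate
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    rounds <- r
    sub <- subset_sites(gm, retained)
    assess <- rf_assess_mutations(sub, labels, n_trees = n_trees,
                                  seed = seed, cv_folds = cv_folds)
    cut <- quantile(assess$scores$gini, gini_quantile, names = FALSE)
    pass_gini <- assess$scores$site[assess$scores$gini >= cut]
    consistent <- colnames(sub$genotype)[
      .clone_consistent(sub$genotype, labels)]
    new_retained <- intersect(pass_gini, consistent)
    if (!length(new_retained)) {
      warning("refinement retained no mutations; falling back to candidate")
      final <- candidate
      final$retained_sites <- retained
      final$scores <- assess$scores
      final$cv_accuracy <- assess$cv_accuracy
      final$rounds <- rounds
      return(final)
    }
    new_retained <- intersect(retained, new_retained)  # never grows
    if (length(new_retained) < 3) break   # too few sites to re-cluster on
    sub2 <- subset_sites(gm, new_retained)
    d <- manhattan_distances(sub2, min_overlap = min_overlap)
    cand2 <- tryCatch(
      hierarchical_clones(d, k_range = k_range,
                          complexity_penalty = complexity_penalty),
      error = function(e) NULL)
    if (is.null(cand2)) break  # degenerate distances: keep current labels
    fixed <- identical(unname(cand2$labels), unname(labels))
    retained <- new_retained
    labels <- cand2$labels
    final <- cand2
    if (fixed) break   # clone labels stable: refinement has converged
  }
  final$retained_sites <- retained
  final$scores <- assess$scores
  final$cv_accuracy <- assess$cv_accuracy
  final$cv_by_class <- assess$cv_by_class
  final$rounds <- rounds
  final
}

#' Row/column orderings for the variant-cell heatmap
#'
#' Cells are grouped by clone (tree order); mutations are ordered so that
#' sites shared by more clones come first (trunk on top), then by the clone
#' where the mutation is most prevalent, then by decreasing prevalence —
#' displaying the stepwise accumulation of mutations along the clonal
#' structure.
#'
#' @param gm a `genotype_matrix`.
#' @param assignment a `clonal_assignment` covering the matrix cells.
#' @return list with `cell_order` and `site_order` (character vectors).
#' @export
order_variant_cell_map <- function(gm, assignment) {
  stopifnot(inherits(gm, "genotype_matrix"))
  labels <- assignment$labels
  if (is.null(labels) || !length(labels)) stop("empty assignment")
  G <- gm$genotype
  cells <- gm$cells
  lab <- labels[cells]
  if (anyNA(lab)) lab <- labels[match(cells, names(labels))]
  clone_order <- order(lab)
  cell_order <- cells[clone_order]

  y <- factor(lab)
  prev <- sapply(levels(y), function(l)
    colMeans(G[y == l, , drop = FALSE] > 0, na.rm = TRUE))
  if (is.null(dim(prev))) prev <- matrix(prev, ncol = nlevels(y),
                                         dimnames = list(colnames(G), levels(y)))
  prev[is.na(prev)] <- 0
  n_high <- rowSums(prev > 0.5)
  top_clone <- max.col(prev, ties.method = "first")
  overall <- colMeans(G > 0, na.rm = TRUE)
  site_order <- colnames(G)[order(-n_high, top_clone, -overall)]
  list(cell_order = cell_order, site_order = site_order)
}

#' Write a clonal tree in Newick form
#'
#' Collapses the cell-level UPGMA tree to clone-level tips (each clone a
#' tip named `clone_<k>`), for downstream clonal-diagram drawing.
#'
#' @param assignment a `clonal_assignment`.
#' @return a Newick string.
#' @export
clone_newick <- function(assignment) {
  hc <- assignment$hclust
  labels <- assignment$labels
  if (is.null(hc)) stop("assignment has no tree")
  # mean inter-clone distance from the cophenetic distances
  coph <- as.matrix(stats::cophenetic(hc))
  lv <- sort(unique(labels))
  k <- length(lv)
  if (k == 1) return(paste0("(clone_", lv, ");"))
  D <- matrix(0, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    D[i, j] <- mean(coph[labels == lv[i], labels == lv[j]])
  }
  hc2 <- hclust(as.dist(D), method = "average")
  .hc_to_newick(hc2, paste0("clone_", lv))
}

.hc_to_newick <- function(hc, tip_labels) {
  rec <- function(i) {
    if (i < 0) return(tip_labels[-i])
    paste0("(", rec(hc$merge[i, 1]), ",", rec(hc$merge[i, 2]), ")")
  }
  paste0(rec(nrow(hc$merge)), ";")
}
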