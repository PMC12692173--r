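## Drop-out imputation by borrowing genotypes from neighboring cells.

#' Missing-aware scaled Manhattan distances between cells
#'
#' For cells i and j the distance is the Manhattan distance over sites
#' observed in both, rescaled to the full site count:
#' `d(i,j) = sum_obs |g_i - g_j| * n_sites / overlap`. Pairs sharing fewer
#' than `min_overlap` observed sites are incomparable and returned as `NA`.
#'
#' @param gm a `genotype_matrix` or a plain numeric matrix with `NA` missing.
#' @param min_overlap minimum shared observed sites for a comparable pair.
#' @return list of class `cell_distances` with `d` (symmetric matrix, zero
#'   diagonal, `NA` incomparable) and `overlap` (shared-site counts).
#' @export
manhattan_distances <- function(gm, min_overlap = 5) {
  G <- if (inherits(gm, "genotype_matrix")) gm$genotype else as.matrix(gm)
  if (nrow(G) < 2) stop("need at least 2 cells")
  mode(G) <- "numeric"
  obs <- !is.na(G)
  G0 <- G
  G0[!obs] <- 0
  # sum |gi - gj| over shared support, computed from genotype levels:
  # |a-b| over {0,1,2} = a + b - 2*min(a,b); use indicator expansion instead
  # for a fully vectorized form: |a-b| = sum_t (I[a>=t] != I[b>=t]), t=1,2
  n_sites <- ncol(G)
  O <- obs %*% t(obs)                      # pairwise observed overlap
  raw <- matrix(0, nrow(G), nrow(G))
  for (t in 1:2) {
    A <- (G0 >= t) & obs
    # mismatches on shared support: A_i(1-A_j) + (1-A_i)A_j restricted to obs
    Ao <- A * 1
    Bo <- (obs & !A) * 1
    raw <- raw + Ao %*% t(Bo) + Bo %*% t(Ao)
  }
  d <- raw * n_sites / O
  d[O < min_overlap] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(G), rownames(G))
  structure(list(d = d, overlap = O, n_sites = n_sites,
                 min_overlap = min_overlap),
            class = "cell_distances")
}

#' Neighbor graph for drop-out imputation
#'
#' Neighbors of cell i are the comparable cells within the `dist_quantile`
#' quantile of i's distances, optionally restricted to cells with the same
#' annotation and to cells whose 96-context signature cosine with i is at
#' least `sig_floor`. Weights are `1 / (1 + d)`.
#'
#' @param distances a `cell_distances` object.
#' @param annotations optional data.frame with columns `cell_id`,
#'   `cell_type`; required when `same_type = TRUE`.
#' @param signature_profiles optional cells x 96 matrix of per-cell spectra.
#' @param dist_quantile neighborhood quantile of each cell's distances.
#' @param same_type restrict neighbors to same-annotation cells.
#' @param sig_floor minimum signature cosine (0 disables).
#' @return list of class `neighbor_graph`: per-cell character vectors of
#'   neighbor ids and numeric weight vectors.
#' @export
find_neighbors <- function(distances, annotations = NULL,
                           signature_profiles = NULL,
                           dist_quantile = 0.15, same_type = FALSE,
                           sig_floor = 0) {
  stopifnot(inherits(distances, "cell_distances"))
  D <- distances$d
  cells <- rownames(D)
  if (is.null(cells)) cells <- as.character(seq_len(nrow(D)))
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- setNames(as.character(annotations$cell_type),
                    as.character(annotations$cell_id))[cells]
  }
  if (same_type && is.null(ann)) stop("same_type = TRUE requires annotations")
  nb <- wt <- vector("list", length(cells))
  names(nb) <- names(wt) <- cells
  for (i in seq_along(cells)) {
    di <- D[i, ]
    cand <- which(!is.na(di) & seq_along(di) != i)
    if (length(cand)) {
      thr <- quantile(di[cand], dist_quantile, names = FALSE)
      cand <- cand[di[cand] <= thr]
    }
    if (same_type && length(cand)) {
      cand <- cand[!is.na(ann[cand]) & !is.na(ann[i]) & ann[cand] == ann[i]]
    }
    if (sig_floor > 0 && !is.null(signature_profiles) && length(cand)) {
      si <- signature_profiles[cells[i], ]
      if (sum(si) > 0) {
        cs <- vapply(cand, function(j) {
          sj <- signature_profiles[cells[j], ]
          if (sum(sj) == 0) return(NA_real_)
          cosine_similarity(si, sj)
        }, numeric(1))
        cand <- cand[!is.na(cs) & cs >= sig_floor]
      }
    }
    if (!length(cand)) {
      .cs_log("cell ", cells[i], " has no eligible neighbors; imputation skipped")
    }
    nb[[i]] <- cells[cand]
    wt[[i]] <- 1 / (1 + D[i, cand])
  }
  structure(list(neighbors = nb, weights = wt,
                 params = list(dist_quantile = dist_quantile,
                               same_type = same_type, sig_floor = sig_floor)),
            class = "neighbor_graph")
}

#' Fill missing genotypes from neighboring cells
#'
#' Only missing entries are ever changed. A missing entry (i, s) is set to
#' the weighted-majority genotype among i's neighbors observed at s when at
#' least `min_votes` neighbors vote and the weighted majority is unique;
#' ties leave the entry missing (conservative).
#'
#' @param gm a `genotype_matrix`.
#' @param graph a `neighbor_graph` built on the same cells.
#' @param min_votes minimum number of observed neighbor genotypes.
#' @return the smoothed `genotype_matrix`; attribute `imputed` carries the
#'   per-cell count of filled entries.
#' @export
impute_dropouts <- function(gm, graph, min_votes = 3) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(graph, "neighbor_graph"))
  G <- gm$genotype
  cells <- gm$cells
  if (!all(cells %in% names(graph$neighbors))) {
    stop("graph does not cover all cells in the matrix")
  }
  out <- G
  filled <- setNames(integer(length(cells)), cells)
  for (i in seq_along(cells)) {
    nbs <- graph$neighbors[[cells[i]]]
    if (!length(nbs)) next
    w <- graph$weights[[cells[i]]]
    ni <- match(nbs, cells)
    keep <- !is.na(ni)
    ni <- ni[keep]; w <- w[keep]
    if (!length(ni)) next
    miss <- which(is.na(G[i, ]))
    if (!length(miss)) next
    sub <- G[ni, miss, drop = FALSE]
    votes <- colSums(!is.na(sub))
    fillable <- which(votes >= min_votes)
    for (s in fillable) {
      g <- sub[, s]
      ok <- !is.na(g)
      tw <- tapply(w[ok], factor(g[ok], levels = c(0, 1, 2)), sum)
      tw[is.na(tw)] <- 0
      top <- which(tw == max(tw))
      if (length(top) == 1) {
        out[i, miss[s]] <- as.integer(names(tw)[top])
        filled[i] <- filled[i] + 1L
      }
    }
  }
  gm$genotype <- out
  attr(gm, "imputed") <- filled
  gm
}
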