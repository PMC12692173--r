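## Robust PCA (principal component pursuit) via inexact augmented Lagrange
## multipliers, with optional masking of missing entries. The genotype
## matrix of a clonal population is approximately low rank (cells in a clone
## share a genotype row pattern) while cell-private noise genotypes are
## sparse, so M = L + S separates structure from noise.

.svt <- function(X, tau) {
  # singular value thresholding
  sv <- svd(X)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(list(L = matrix(0, nrow(X), ncol(X)), rank = 0L))
  L <- sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
  list(L = L, rank = sum(keep))
}

.shrink <- function(X, tau) sign(X) * pmax(abs(X) - tau, 0)

#' Robust PCA decomposition M = L + S
#'
#' Principal component pursuit solved by inexact augmented-Lagrange
#' iterations: minimize `||L||_* + lambda ||S||_1` subject to `L + S = M`
#' on the observed entries. Missing entries (`NA` in `M`) are unconstrained:
#' the residual and dual updates are restricted to the observed support.
#'
#' @param M numeric matrix; `NA` marks missing entries.
#' @param lambda sparsity weight; default `1 / sqrt(max(dim(M)))`.
#' @param tol relative Frobenius tolerance on the observed residual.
#' @param max_iter iteration cap; non-convergence returns a result with
#'   `converged = FALSE` and a warning.
#' @return list of class `rpca_result`: `L`, `S`, `lambda`, `iterations`,
#'   `converged`, `residual` (relative), `rank` of `L`.
#' @export
rpca_decompose <- function(M, lambda = NULL, tol = 1e-7, max_iter = 500) {
  M <- as.matrix(M)
  mode(M) <- "numeric"
  if (length(M) == 0) stop("empty matrix")
  obs <- !is.na(M)
  if (!any(obs)) stop("matrix has no observed entries")
  if (is.null(lambda)) lambda <- 1 / sqrt(max(dim(M)))
  M0 <- M
  M0[!obs] <- 0
  normM <- sqrt(sum(M0^2))
  if (normM == 0) {
    Z <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
    return(structure(list(L = Z, S = Z, lambda = lambda, iterations = 0L,
                          converged = TRUE, residual = 0, rank = 0L),
                     class = "rpca_result"))
  }
  sigma1 <- svd(M0, nu = 0, nv = 0)$d[1]
  mu <- 1.25 / sigma1
  mu_bar <- mu * 1e7
  rho <- 1.5
  # dual initialization scaled as in the standard inexact-ALM scheme
  J <- max(sigma1, max(abs(M0)) / lambda)
  Y <- M0 / J
  S <- matrix(0, nrow(M), ncol(M))
  L <- S
  converged <- FALSE
  it <- 0L
  rankL <- 0L
  res <- Inf
  Mw <- M0                             # working copy; missing entries are
  while (it < max_iter) {              # imputed with L + S each iteration
    it <- it + 1L
    sv <- .svt(Mw - S + Y / mu, 1 / mu)
    L <- sv$L
    rankL <- sv$rank
    S <- .shrink(Mw - L + Y / mu, lambda / mu)
    Mw[!obs] <- (L + S)[!obs]
    Z <- Mw - L - S                    # zero on the missing support
    res <- sqrt(sum(Z^2)) / normM
    if (res < tol) { converged <- TRUE; break }
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
  }
  if (!converged) {
    warning("RPCA did not converge in ", max_iter,
            " iterations (residual ", signif(res, 3), ")")
  }
  dimnames(L) <- dimnames(S) <- dimnames(M)
  structure(list(L = L, S = S, lambda = lambda, iterations = it,
                 converged = converged, residual = res, rank = rankL),
            class = "rpca_result")
}

#' @export
print.rpca_result <- function(x, ...) {
  cat("rpca_result: rank(L) =", x$rank, "| iterations =", x$iterations,
      "| residual =", signif(x$residual, 3),
      "| converged =", x$converged, "\n")
  invisible(x)
}

.quantize_genotype <- function(x) {
  # nearest of {0,1,2} with 0.5 boundaries
  g <- round(pmin(pmax(x, 0), 2))
  storage.mode(g) <- "integer"
  g
}

#' Denoise a genotype matrix with robust PCA
#'
#' Decomposes the (smoothed) genotype matrix into low-rank clonal structure
#' L and sparse noise S. Observed entries whose sparse component exceeds
#' `sparse_cut` in magnitude are reset to the re-quantized low-rank value;
#' other observed entries are kept. Missing entries stay missing. Columns
#' that are entirely missing are dropped.
#'
#' @param gm a `genotype_matrix`.
#' @param lambda,tol,max_iter passed to [rpca_decompose()].
#' @param sparse_cut magnitude of S above which an entry is treated as noise.
#' @param continuous if `TRUE` also return the continuous low-rank matrix.
#' @return the denoised `genotype_matrix`; attribute `rpca` carries the
#'   decomposition diagnostics.
#' @export
denoise_matrix <- function(gm, lambda = NULL, tol = 1e-7, max_iter = 500,
                           sparse_cut = 0.5, continuous = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  G <- gm$genotype
  if (length(G) == 0 || all(is.na(G))) stop("empty matrix")
  empty_col <- colSums(!is.na(G)) == 0
  if (any(empty_col)) {
    .cs_log(sum(empty_col), " all-missing site columns dropped")
    gm <- subset_sites(gm, !empty_col)
    G <- gm$genotype
  }
  dec <- rpca_decompose(G, lambda = lambda, tol = tol, max_iter = max_iter)
  Lq <- .quantize_genotype(dec$L)
  out <- G
  noisy <- !is.na(G) & abs(dec$S) > sparse_cut
  out[noisy] <- Lq[noisy]
  # degenerate collapse guard: with very few cells the nuclear penalty can
  # flatten every cell onto one pattern, erasing real structure; when that
  # rewrites a large share of the observed entries, denoising is a no-op
  # (removing a handful of private entries legitimately yields one pattern)
  rows <- apply(out, 1, paste, collapse = ",")
  changed <- mean(out[!is.na(G)] != G[!is.na(G)])
  if (nrow(out) >= 2 && length(unique(rows)) == 1 && changed > 0.2 &&
      length(unique(apply(G, 1, paste, collapse = ","))) > 1) {
    warning("RPCA collapsed all cells onto one genotype pattern; ",
            "returning the input matrix unchanged")
    attr(gm, "rpca") <- dec
    return(gm)
  }
  gm$genotype <- out
  attr(gm, "rpca") <- dec
  if (continuous) attr(gm, "L") <- dec$L
  gm
}

#' Drop sites mutated in too few cells
#'
#' Exclusive genotypes carried by fewer than `min_cells` cells are removed
#' as presumptive noise.
#'
#' @param gm a `genotype_matrix`.
#' @param min_cells minimum cells with a nonzero genotype to keep a site.
#' @return the reduced `genotype_matrix`; attribute `dropped_sites` lists
#'   removed site keys.
#' @export
drop_rare_sites <- function(gm, min_cells = 3) {
  stopifnot(inherits(gm, "genotype_matrix"), min_cells >= 1)
  nz <- colSums(gm$genotype > 0, na.rm = TRUE)
  keep <- nz >= min_cells
  dropped <- colnames(gm$genotype)[!keep]
  gm <- subset_sites(gm, keep)
  attr(gm, "dropped_sites") <- dropped
  gm
}

#' Subset the site columns of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @param keep logical/integer/character column selector.
#' @return the subset `genotype_matrix`.
#' @export
subset_sites <- function(gm, keep) {
  gm$genotype <- gm$genotype[, keep, drop = FALSE]
  gm$ref_count <- gm$ref_count[, keep, drop = FALSE]
  gm$alt_count <- gm$alt_count[, keep, drop = FALSE]
  gm$sites <- gm$sites[match(colnames(gm$genotype), gm$sites$site_key), ]
  gm
}
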