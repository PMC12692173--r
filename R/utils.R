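## Shared helpers: logging, site keys, small numeric utilities.

.cs_log <- function(..., verbose = getOption("clonescope.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[clonescope] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  # vectorized reverse complement of short uppercase strings
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(.complement[b])), collapse = "")
  }, character(1))
}

#' Cosine similarity between two non-negative vectors
#'
#' Standard inner-product cosine. Scale invariant, so counts and normalized
#' fractions give the same value.
#'
#' @param a,b numeric vectors of equal length, not all zero.
#' @return similarity in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

# nondecreasing integer check
.is_nondecreasing <- function(x) all(diff(x) >= 0)

# stratified fold assignment, deterministic under set.seed upstream
.stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# area under the ROC curve via the rank-sum statistic
.auroc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
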