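# Shared fixtures and independent oracles for the test suite.

# independent beta-binomial log pmf straight from log-gamma functions
bb_logpmf_oracle <- function(k, n, mu, s) {
  a <- mu * s; b <- (1 - mu) * s
  (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)) +
    (lgamma(k + a) + lgamma(n - k + b) - lgamma(n + a + b)) +
    (lgamma(a + b) - lgamma(a) - lgamma(b))
}

# brute-force pair-counting clustering indices
pair_count_oracle <- function(labels, reference) {
  n <- length(labels)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_l <- labels[i] == labels[j]
    same_r <- reference[i] == reference[j]
    if (same_l && same_r) s11 <- s11 + 1
    else if (same_l && !same_r) s10 <- s10 + 1
    else if (!same_l && same_r) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  total <- n * (n - 1) / 2
  PA <- s11 + s10; PB <- s11 + s01
  expected <- PA * PB / total
  maxi <- (PA + PB) / 2
  ari <- if (maxi == expected) as.numeric(s11 == expected)
         else (s11 - expected) / (maxi - expected)
  fm <- if (PA == 0 || PB == 0) 0 else s11 / sqrt(PA * PB)
  list(ari = ari, fm = fm)
}

# brute-force NMI from the definition
nmi_oracle <- function(labels, reference) {
  ct <- table(labels, reference)
  n <- sum(ct)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    if (ct[i, j] > 0) {
      mi <- mi + ct[i, j] / n *
        log(ct[i, j] * n / (sum(ct[i, ]) * sum(ct[, j])))
    }
  }
  h <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  hu <- h(rowSums(ct)); hv <- h(colSums(ct))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi / sqrt(hu * hv)
}

# all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# brute-force alternating-shrinkage robust PCA (reference implementation,
# structured differently from the package's inexact-ALM solver)
rpca_brute <- function(M, lambda = 1 / sqrt(max(dim(M))), iters = 2000) {
  Y <- M / max(svd(M, nu = 0, nv = 0)$d[1], max(abs(M)) / lambda)
  mu <- 1.25 / svd(M, nu = 0, nv = 0)$d[1]
  S <- matrix(0, nrow(M), ncol(M))
  L <- S
  for (it in seq_len(iters)) {
    sv <- svd(M - S + Y / mu)
    dd <- pmax(sv$d - 1 / mu, 0)
    L <- sv$u %*% diag(dd, length(dd)) %*% t(sv$v)
    R <- M - L + Y / mu
    S <- sign(R) * pmax(abs(R) - lambda / mu, 0)
    Z <- M - L - S
    if (sqrt(sum(Z^2)) / max(sqrt(sum(M^2)), 1e-12) < 1e-9) break
    Y <- Y + mu * Z
    mu <- min(mu * 1.5, mu * 1e7)
  }
  list(L = L, S = S)
}

# small genotype_matrix from a plain matrix (counts layers synthesized)
gm_from_matrix <- function(G) {
  if (is.null(rownames(G))) rownames(G) <- sprintf("c%02d", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <-
      sprintf("chrT:%d:A:G", seq_len(ncol(G)) * 10L)
  sites <- data.table::data.table(
    chrom = "chrT", pos = seq_len(ncol(G)) * 10L, ref = "A", alt = "G",
    site_key = colnames(G))
  RC <- matrix(ifelse(is.na(G), NA_real_, 10), nrow(G), ncol(G),
               dimnames = dimnames(G))
  AC <- matrix(ifelse(is.na(G), NA_real_, G * 5), nrow(G), ncol(G),
               dimnames = dimnames(G))
  structure(list(genotype = G, ref_count = RC, alt_count = AC,
                 cells = rownames(G), sites = sites),
            class = "genotype_matrix")
}

# cached small read-level simulation shared across test files
small_bam_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "clonescope_small_sim")
      cache <<- write_synthetic_bam(
        dir,
        params = list(n_cells = 24, n_clones = 3, n_clonal_sites = 36,
                      n_germline_sites = 40, n_editing_sites = 40,
                      n_mbs_sites = 8, n_genes = 10, gene_length = 800,
                      contig_length = 2e4),
        seed = 7)
    }
    cache
  }
})

# write a SAM built from explicit read tuples and convert to BAM
write_test_bam <- function(reads, contig = "chrT", contig_len = 1000,
                           path = tempfile()) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  body <- vapply(reads, function(r) {
    qual <- if (!is.null(r$qual)) r$qual else
      paste(rep("I", nchar(r$seq)), collapse = "")   # Q40
    fields <- c(r$qname, r$flag %||% 0L, contig, r$pos, r$mapq %||% 60L,
                r$cigar %||% paste0(nchar(r$seq), "M"), "*", 0L, 0L,
                r$seq, qual)
    if (!is.null(r$cb)) fields <- c(fields, paste0("CB:Z:", r$cb))
    paste(fields, collapse = "\t")
  }, character(1))
  sam <- paste0(path, ".sam")
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, path, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FASTA reference written from an explicit sequence
write_test_fasta <- function(seq, contig = "chrT", path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seq, contig)), path)
  Rsamtools::indexFa(path)
  path
}
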