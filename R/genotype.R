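## Beta-binomial genotype inference.
##
## At a variant site in one cell the alternate read count k out of depth n is
## modelled as BetaBinomial(n, mu_g, s) where the mean mu_g depends on the
## true genotype g: mu_0 = epsilon (sequencing error), mu_1 = rho (the
## expected alternate fraction of a heterozygous site, 0.5 absent allelic
## imbalance), mu_2 = 1 - epsilon. The concentration s controls
## overdispersion relative to a binomial (s -> Inf recovers the binomial).

#' Beta-binomial log pmf
#'
#' Mean/concentration parameterization: `alpha = mu * s`, `beta = (1 - mu) * s`.
#'
#' @param k alternate count(s).
#' @param n total depth(s).
#' @param mu mean alternate fraction in (0, 1).
#' @param s concentration (> 0); larger is closer to binomial.
#' @return log probability mass, vectorized over `k`/`n`.
#' @export
dbetabinom_log <- function(k, n, mu, s) {
  a <- mu * s
  b <- (1 - mu) * s
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Posterior over genotypes {0, 1, 2} from allele counts
#'
#' Computes the beta-binomial likelihood of the observed alternate count
#' under wild-type (mean `epsilon`), heterozygous (mean `rho`, the
#' allelic-imbalance-adjusted alternate fraction) and homozygous
#' (mean `1 - epsilon`) genotypes, combines with the prior and returns the
#' normalized posterior. The called genotype is the argmax when the maximum
#' posterior reaches `confidence`, otherwise `NA` (ambiguous evidence).
#'
#' @param ref_count,alt_count non-negative reference / alternate read counts.
#' @param rho expected heterozygous alternate fraction, in (0, 1).
#' @param epsilon per-base error rate, in (0, 0.1].
#' @param overdispersion beta-binomial concentration s (> 0).
#' @param prior length-3 prior over genotypes 0/1/2 (normalized internally).
#' @param confidence minimum posterior mass to emit a hard genotype call.
#' @return list with `posterior` (named numeric, sums to 1) and `genotype`
#'   (0, 1, 2 or `NA`). Zero total depth yields `genotype = NA` and a
#'   posterior equal to the prior.
#' @export
genotype_posterior <- function(ref_count, alt_count, rho = 0.5,
                               epsilon = 0.001, overdispersion = 100,
                               prior = c(1, 1, 1) / 3, confidence = 0.8) {
  stopifnot(ref_count >= 0, alt_count >= 0, epsilon > 0, epsilon <= 0.1,
            overdispersion > 0, length(prior) == 3, all(prior >= 0))
  prior <- prior / sum(prior)
  n <- ref_count + alt_count
  if (n == 0) {
    post <- setNames(prior, c("0", "1", "2"))
    return(list(posterior = post, genotype = NA_integer_))
  }
  rho <- min(max(rho, 0.05), 0.95)
  ll <- c(dbetabinom_log(alt_count, n, epsilon, overdispersion),
          dbetabinom_log(alt_count, n, rho, overdispersion),
          dbetabinom_log(alt_count, n, 1 - epsilon, overdispersion))
  lp <- ll + log(prior)
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))
  names(post) <- c("0", "1", "2")
  g <- unname(which.max(post)) - 1L
  if (post[[g + 1L]] < confidence) g <- NA_integer_
  list(posterior = post, genotype = g)
}

# vectorized genotype call over parallel count vectors; returns integer vector
.genotype_calls <- function(ref, alt, rho, epsilon, overdispersion,
                            prior0, confidence) {
  n <- ref + alt
  out <- rep(NA_integer_, length(n))
  ok <- n > 0
  if (!any(ok)) return(out)
  rho <- pmin(pmax(rho, 0.05), 0.95)
  if (length(rho) == 1) rho <- rep(rho, length(n))
  ll0 <- dbetabinom_log(alt[ok], n[ok], epsilon, overdispersion)
  ll1 <- dbetabinom_log(alt[ok], n[ok], rho[ok], overdispersion)
  ll2 <- dbetabinom_log(alt[ok], n[ok], 1 - epsilon, overdispersion)
  if (is.null(dim(prior0))) {
    lp <- cbind(ll0 + log(prior0[1]), ll1 + log(prior0[2]), ll2 + log(prior0[3]))
  } else {
    lp <- cbind(ll0, ll1, ll2) + log(prior0[ok, , drop = FALSE])
  }
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p <- p / rowSums(p)
  g <- max.col(p, ties.method = "first") - 1L
  conf <- p[cbind(seq_len(nrow(p)), g + 1L)]
  g[conf < confidence] <- NA_integer_
  out[ok] <- g
  out
}

#' Build a cell-by-site genotype matrix from filtered calls
#'
#' Entries are observed wherever read counts exist for a (cell, site) pair;
#' each observed entry is genotyped with [genotype_posterior()]. Cells with
#' fewer than `min_sites` observed genotypes are dropped (too little
#' evidence for clonal placement).
#'
#' @param counts data.frame/data.table with columns `cell_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `ref_count`, `alt_count` (one row per observed
#'   cell-site pair; sites may also carry `gene` for imbalance lookup).
#' @param imbalance optional data.frame with columns `gene`, `rho` and
#'   optionally `expression_rate`; genes absent default to `rho = 0.5`.
#' @param epsilon,overdispersion,confidence see [genotype_posterior()].
#' @param min_sites minimum observed genotypes to keep a cell.
#' @param use_expression_rate if `TRUE`, the prior odds of genotype 0 are
#'   multiplied by the gene's expression rate (floored at 0.1), discounting
#'   wild-type calls at drop-out-prone genes.
#' @return object of class `genotype_matrix`: list with integer matrix
#'   `genotype` (cells x sites, `NA` = missing), matrices `ref_count`,
#'   `alt_count`, `cells`, and data.table `sites`.
#' @export
build_genotype_matrix <- function(counts, imbalance = NULL,
                                  epsilon = 0.001, overdispersion = 100,
                                  confidence = 0.8, min_sites = 10,
                                  use_expression_rate = TRUE) {
  dt <- as.data.table(counts)
  req <- c("cell_id", "chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(req %in% names(dt))) {
    stop("counts must have columns: ", paste(setdiff(req, names(dt)), collapse = ", "))
  }
  dt[, site_key := .site_key(chrom, pos, ref, alt)]
  sites <- unique(dt[, .(chrom, pos, ref, alt, site_key,
                         gene = if ("gene" %in% names(dt)) gene else NA_character_)])
  setorder(sites, chrom, pos, alt)
  cells <- sort(unique(dt$cell_id))

  rho <- rep(0.5, nrow(dt))
  prior <- c(1, 1, 1) / 3
  prior_mat <- NULL
  if (!is.null(imbalance) && "gene" %in% names(dt)) {
    imb <- as.data.table(imbalance)
    m <- match(dt$gene, imb$gene)
    hit <- !is.na(m)
    if ("rho" %in% names(imb)) rho[hit] <- imb$rho[m[hit]]
    if (use_expression_rate && "expression_rate" %in% names(imb)) {
      er <- rep(1, nrow(dt))
      er[hit] <- pmax(imb$expression_rate[m[hit]], 0.1)
      prior_mat <- cbind(prior[1] * er, prior[2], prior[3])
      prior_mat <- prior_mat / rowSums(prior_mat)
    }
  }
  rho <- pmin(pmax(rho, 0.05), 0.95)

  g <- .genotype_calls(dt$ref_count, dt$alt_count, rho, epsilon,
                       overdispersion,
                       if (is.null(prior_mat)) prior else prior_mat,
                       confidence)

  i <- match(dt$cell_id, cells)
  j <- match(dt$site_key, sites$site_key)
  nm <- list(cells, sites$site_key)
  G <- matrix(NA_integer_, length(cells), nrow(sites), dimnames = nm)
  RC <- matrix(NA_real_, length(cells), nrow(sites), dimnames = nm)
  AC <- matrix(NA_real_, length(cells), nrow(sites), dimnames = nm)
  G[cbind(i, j)] <- g
  RC[cbind(i, j)] <- dt$ref_count
  AC[cbind(i, j)] <- dt$alt_count

  n_obs <- rowSums(!is.na(G))
  keep <- n_obs >= min_sites
  if (!any(keep)) {
    stop("all cells dropped: no cell has >= ", min_sites,
         " observed genotypes (min_sites)")
  }
  if (any(!keep)) {
    .cs_log(sum(!keep), " cells dropped (< ", min_sites, " observed sites)")
  }
  structure(
    list(genotype = G[keep, , drop = FALSE],
         ref_count = RC[keep, , drop = FALSE],
         alt_count = AC[keep, , drop = FALSE],
         cells = cells[keep],
         sites = sites,
         dropped_cells = cells[!keep]),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$cells), "cells x", nrow(x$sites), "sites;",
      round(100 * mean(is.na(x$genotype)), 1), "% missing\n")
  invisible(x)
}

#' Raw VAF and inferred-genotype spectra
#'
#' Returns the raw variant-allele-fraction histogram from the count layers
#' and the distribution of inferred genotypes. After inference the spectrum
#' collapses onto {0, 1, 2}; heterozygous peaks that are smeared in raw VAF
#' by sampling noise and allelic imbalance become a single class.
#'
#' @param gm a `genotype_matrix`.
#' @param breaks histogram breaks over `[0, 1]`.
#' @return list with `raw` (histogram counts per bin, plus `mids`) and
#'   `genotype` (table over 0/1/2).
#' @export
vaf_histogram <- function(gm, breaks = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- gm$ref_count + gm$alt_count
  ok <- !is.na(n) & n > 0
  if (!any(ok)) stop("empty matrix: no observed counts")
  v <- gm$alt_count[ok] / n[ok]
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(raw = list(counts = h$counts, mids = h$mids),
       genotype = table(factor(gm$genotype[!is.na(gm$genotype)],
                               levels = c(0, 1, 2))))
}
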