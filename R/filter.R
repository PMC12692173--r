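## SVM-based separation of genuine mutations from RNA-editing artifacts and
## sequencing errors. Positives: calls catalogued in a dbSNP-like resource
## with population frequency >= common_af. Negatives: calls at known
## RNA-editing sites whose annotated function is not amino-acid-changing,
## plus all multi-base substitution calls. Everything else is the
## prediction set scored by the trained decision function.

.NUM_FEATURES <- c("depth", "alt_count", "vaf", "vaf_ci_low",
                   "mean_base_qual", "site_quality", "genotype_quality",
                   "calibrated_genotype_quality", "strand_bias_ratio",
                   "cell_support", "editing_neighbors")

# number of catalogued editing sites within +/- `neighborhood` bp of each
# call, not counting the call's own position
.editing_neighbors <- function(dt, editing_sites, neighborhood) {
  if (is.null(editing_sites)) return(rep(0, nrow(dt)))
  ed <- as.data.table(editing_sites)
  out <- numeric(nrow(dt))
  for (ch in unique(dt$chrom)) {
    ep <- sort(ed[chrom == ch, pos])
    sel <- which(dt$chrom == ch)
    if (!length(ep) || !length(sel)) next
    pp <- dt$pos[sel]
    n_in <- findInterval(pp + neighborhood, ep) -
      findInterval(pp - neighborhood - 1L, ep)
    self <- pp %in% ep
    out[sel] <- n_in - as.integer(self)
  }
  out
}

# Wilson score lower bound of the allele fraction: a depth-aware VAF that
# discounts fractions inflated by binomial noise at low depth
.wilson_low <- function(k, n, z = 1.96) {
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  (centre - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / denom
}
.SUB_LEVELS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G", "MBS", "indel")
.REGION_LEVELS <- c("exonic", "intronic", "UTR3", "UTR5", "intergenic",
                    "splicing", "ncRNA")
.EXFUNC_LEVELS <- c("synonymous", "nonsynonymous", "stopgain", "unknown")

#' Feature matrix for the mutation filter
#'
#' Numeric features (depth, alt count, VAF and its Wilson lower bound, base
#' quality, site quality, genotype qualities, strand-bias ratio, cross-cell
#' site support, and the number of catalogued editing sites in the call's
#' neighborhood — A-to-I editing clusters in inverted Alu repeats, so
#' proximity to known editing is itself evidence of artifact) plus one-hot
#' blocks for substitution class, region class and exonic function.
#' Genotype-quality fields absent from pileup calls are imputed as 0 and
#' flagged in the result's `imputed_features` attribute.
#'
#' @param table a `variant_table`.
#' @param editing_sites optional data.frame with `chrom`, `pos` of catalogued
#'   RNA-editing sites, used for the neighborhood feature (`NULL` = 0).
#' @param neighborhood half-width (bp) of the editing-neighborhood window.
#' @return numeric matrix, one row per call.
#' @export
call_features <- function(table, editing_sites = NULL, neighborhood = 30L) {
  dt <- as.data.table(table)
  dt[, site_key := .site_key(chrom, pos, ref, alt)]
  support <- dt[, .(cell_support = uniqueN(cell_id)), by = site_key]
  dt <- support[dt, on = "site_key"]
  mq <- ifelse(is.na(dt$mean_base_qual), 0, dt$mean_base_qual)
  f <- dt$strand_alt_fwd; r <- dt$strand_alt_rev
  sb <- ifelse(is.na(f) | is.na(r) | (f + r) == 0, 0.5,
               pmin(f, r) / pmax(f + r, 1))
  num <- cbind(depth = dt$depth, alt_count = dt$alt_count, vaf = dt$vaf,
               vaf_ci_low = .wilson_low(dt$alt_count, dt$depth),
               mean_base_qual = mq,
               site_quality = dt$alt_count * mq,
               genotype_quality = if ("genotype_quality" %in% names(dt))
                 ifelse(is.na(dt$genotype_quality), 0, dt$genotype_quality)
               else 0,
               calibrated_genotype_quality =
                 if ("calibrated_genotype_quality" %in% names(dt))
                   ifelse(is.na(dt$calibrated_genotype_quality), 0,
                          dt$calibrated_genotype_quality)
               else 0,
               strand_bias_ratio = sb,
               cell_support = dt$cell_support,
               editing_neighbors = .editing_neighbors(dt, editing_sites,
                                                      neighborhood))
  onehot <- function(x, levels, prefix) {
    x <- ifelse(is.na(x) | !(x %in% levels), levels[length(levels)], x)
    m <- outer(x, levels, `==`) * 1
    colnames(m) <- paste0(prefix, "_", gsub("[^A-Za-z0-9]", "", levels))
    m
  }
  sub <- onehot(dt$substitution_class, .SUB_LEVELS, "sub")
  reg <- onehot(if ("region_class" %in% names(dt)) dt$region_class else
    rep(NA_character_, nrow(dt)), .REGION_LEVELS, "region")
  exf <- onehot(if ("exonic_function" %in% names(dt)) dt$exonic_function else
    rep(NA_character_, nrow(dt)), .EXFUNC_LEVELS, "exfunc")
  X <- cbind(num, sub, reg, exf)
  imputed <- c(if (!("genotype_quality" %in% names(dt))) "genotype_quality",
               if (!("calibrated_genotype_quality" %in% names(dt)))
                 "calibrated_genotype_quality")
  attr(X, "imputed_features") <- imputed
  X
}

#' Read a dbSNP-like VCF into a keyed site table
#' @param vcf path to a VCF with an AF (or CAF) INFO field.
#' @return data.table with chrom, pos, ref, alt, af.
#' @export
read_dbsnp <- function(vcf) {
  v <- VariantAnnotation::readVcf(vcf)
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  af <- if ("AF" %in% names(info)) {
    vapply(info$AF, function(x) as.numeric(x[1]), numeric(1))
  } else if ("CAF" %in% names(info)) {
    vapply(info$CAF, function(x) suppressWarnings(
      1 - as.numeric(x[1])), numeric(1))
  } else rep(NA_real_, length(rr))
  alt <- vapply(as.list(VariantAnnotation::alt(v)), function(a)
    as.character(a[1]), character(1))
  data.table(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(VariantAnnotation::ref(v)),
             alt = alt, af = af)
}

#' Read an RNA-editing site table
#' @param tsv TSV with columns chrom, pos, ref, alt, func.
#' @return data.table.
#' @export
read_editing_sites <- function(tsv) {
  ed <- fread(tsv)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(ed)))
  if (!("func" %in% names(ed))) ed[, func := "unknown"]
  ed
}

#' Assemble the SVM training set from database resources
#'
#' Positives: calls matching a dbSNP-like record with allele frequency at
#' least `common_af` (common germline variation: certainly real sequence).
#' Negatives: calls at known RNA-editing sites whose function is not
#' amino-acid-changing, plus all MBS calls. Sites labelled both ways are
#' dropped. Remaining calls form the prediction set.
#'
#' @param table a `variant_table`.
#' @param dbsnp data.table from [read_dbsnp()] or a VCF path.
#' @param editing data.table from [read_editing_sites()] or a TSV path.
#' @param common_af minimum population frequency for a positive.
#' @return list of class `training_set`: `features` (full matrix), `label`
#'   (factor pos/neg/`NA`), `table` (with `site_key`), counts.
#' @export
build_training_set <- function(table, dbsnp, editing, common_af = 0.01) {
  if (is.character(dbsnp)) dbsnp <- read_dbsnp(dbsnp)
  if (is.character(editing)) editing <- read_editing_sites(editing)
  dt <- as.data.table(table)
  dt[, site_key := .site_key(chrom, pos, ref, alt)]
  pos_keys <- .site_key(dbsnp$chrom, dbsnp$pos, dbsnp$ref,
                        dbsnp$alt)[!is.na(dbsnp$af) & dbsnp$af >= common_af]
  aa_changing <- c("nonsynonymous", "stopgain", "stoploss", "missense")
  ed_ok <- !(tolower(editing$func) %in% aa_changing)
  neg_keys <- .site_key(editing$chrom, editing$pos, editing$ref,
                        editing$alt)[ed_ok]
  label <- rep(NA_character_, nrow(dt))
  label[dt$site_key %in% pos_keys] <- "pos"
  is_neg <- dt$site_key %in% neg_keys | dt$substitution_class %in% "MBS"
  conflict <- is_neg & label %in% "pos"
  if (any(conflict)) {
    .cs_log(sum(conflict), " calls labelled both positive and negative; dropped")
    label[conflict] <- "conflict"
  }
  label[is_neg & is.na(label)] <- "neg"
  n_pos <- sum(label %in% "pos"); n_neg <- sum(label %in% "neg")
  if (n_pos == 0 || n_neg == 0) {
    stop("empty training class (", n_pos, " positives, ", n_neg,
         " negatives); relax common_af or supply more cells")
  }
  X <- call_features(dt, editing_sites = editing)
  structure(list(features = X, label = label, table = dt,
                 n_pos = n_pos, n_neg = n_neg,
                 dbsnp_keys = pos_keys, common_af = common_af,
                 editing_sites = editing[, c("chrom", "pos")]),
            class = "training_set")
}

#' Train the SVM mutation filter
#'
#' RBF-kernel SVM with balanced class weights on z-scored numeric features.
#' Single-valued (degenerate) feature columns are dropped. Held-out
#' performance is reported as the mean AUROC over a stratified 5-fold split.
#'
#' @param training a `training_set` from [build_training_set()].
#' @param kernel,cost passed to [e1071::svm()].
#' @param seed RNG seed; retraining with the same seed gives identical
#'   decision values.
#' @param cv_folds folds for held-out AUROC.
#' @param exclude_features feature columns withheld from the decision
#'   function. By default the cross-cell `cell_support` feature is excluded:
#'   the training classes (shared germline variants vs recurrent editing
#'   sites) are both multi-cell, while genuine somatic mutations in
#'   transcriptome data are mostly private to single cells, so a classifier
#'   leaning on support would not generalize to the prediction set.
#' @return object of class `filter_model`: the fitted svm, feature scaling,
#'   decision-sign alignment and `cv_auroc`.
#' @export
train_filter <- function(training, kernel = "radial", cost = 1, seed = 1,
                         cv_folds = 5, exclude_features = "cell_support") {
  stopifnot(inherits(training, "training_set"))
  lab <- training$label
  tr <- which(lab %in% c("pos", "neg"))
  X <- training$features[tr, , drop = FALSE]
  X <- X[, setdiff(colnames(X), exclude_features), drop = FALSE]
  y <- factor(lab[tr], levels = c("neg", "pos"))
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  if (any(!keep)) {
    .cs_log("dropping degenerate feature columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  cw <- length(y) / (2 * table(y))
  set.seed(seed)
  fit <- e1071::svm(x = Xs, y = y, kernel = kernel, cost = cost,
                    class.weights = cw, scale = FALSE)
  dv <- attr(predict(fit, Xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- mean(dv[y == "pos"]) < mean(dv[y == "neg"])

  # stratified CV: held-out AUROC plus out-of-fold decision values used to
  # calibrate the operating point (Youden's J). The raw sign of the decision
  # function is not a reliable cutoff under balanced class weights: it can
  # sit inside the positive class even when ranking is near-perfect.
  set.seed(seed + 1L)
  fold <- .stratified_folds(y, cv_folds)
  aucs <- rep(NA_real_, cv_folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(cv_folds)) {
    trn <- fold != f
    if (length(unique(y[trn])) < 2 || !any(!trn)) next
    m <- e1071::svm(x = Xs[trn, , drop = FALSE], y = y[trn], kernel = kernel,
                    cost = cost, class.weights = cw, scale = FALSE)
    d <- attr(predict(m, Xs[!trn, , drop = FALSE],
                      decision.values = TRUE), "decision.values")[, 1]
    dtr <- attr(predict(m, Xs[trn, , drop = FALSE],
                        decision.values = TRUE), "decision.values")[, 1]
    if (mean(dtr[y[trn] == "pos"]) < mean(dtr[y[trn] == "neg"])) d <- -d
    aucs[f] <- .auroc(d, y[!trn] == "pos")
    oof[!trn] <- d
  }
  thr <- 0
  ok <- !is.na(oof)
  if (any(ok & y == "pos") && any(ok & y == "neg")) {
    cand <- sort(unique(oof[ok]))
    cuts <- c(cand[1] - 1e-9, (head(cand, -1) + tail(cand, -1)) / 2)
    youden <- vapply(cuts, function(tt) {
      sens <- mean(oof[ok & y == "pos"] >= tt)
      spec <- mean(oof[ok & y == "neg"] < tt)
      sens + spec - 1
    }, numeric(1))
    thr <- cuts[which.max(youden)]
  }
  structure(list(svm = fit, features = colnames(X), center = ctr,
                 scale = scl, flip = flip, seed = seed,
                 cv_auroc = mean(aucs, na.rm = TRUE),
                 threshold = thr,
                 editing_sites = training$editing_sites,
                 n_pos = sum(y == "pos"), n_neg = sum(y == "neg")),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  cat("filter_model: SVM on", length(x$features), "features |",
      x$n_pos, "pos /", x$n_neg, "neg | CV AUROC =",
      round(x$cv_auroc, 3), "\n")
  invisible(x)
}

#' Decision values of the filter for a call table
#' @param model a `filter_model`.
#' @param table a `variant_table` (or `training_set$table`).
#' @return numeric decision values, positive = mutation-like.
#' @export
filter_decision <- function(model, table) {
  X <- call_features(table, editing_sites = model$editing_sites)
  missing <- setdiff(model$features, colnames(X))
  if (length(missing)) {
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  }
  Xs <- scale(X[, model$features, drop = FALSE], center = model$center,
              scale = model$scale)
  dv <- attr(predict(model$svm, Xs, decision.values = TRUE),
             "decision.values")[, 1]
  if (model$flip) dv <- -dv
  unname(dv)
}

#' Retain high-confidence calls
#'
#' Keeps calls whose decision value is at least `decision_threshold`; calls
#' matching the dbSNP-like resource are kept regardless by default
#' (`strict_svm = FALSE`), since low-depth known variants remain useful for
#' genotyping drop-outs. Raising the threshold never adds calls.
#'
#' @param model a `filter_model`.
#' @param table a `variant_table`.
#' @param decision_threshold minimum decision value; `NULL` (default) uses
#'   the model's cross-validation-calibrated operating point.
#' @param dbsnp_keys character site keys treated as always-retained
#'   positives (e.g. `training_set$dbsnp_keys`).
#' @param strict_svm if `TRUE`, database positives must also pass the SVM.
#' @return the filtered `variant_table` with a `decision` column.
#' @export
score_and_filter <- function(model, table, decision_threshold = NULL,
                             dbsnp_keys = NULL, strict_svm = FALSE) {
  if (is.null(decision_threshold)) {
    decision_threshold <- model$threshold %||% 0
  }
  dt <- as.data.table(table)
  dt[, site_key := .site_key(chrom, pos, ref, alt)]
  dv <- filter_decision(model, dt)
  dt[, decision := dv]
  keep <- dv >= decision_threshold
  if (!strict_svm && !is.null(dbsnp_keys)) {
    keep <- keep | dt$site_key %in% dbsnp_keys
  }
  out <- dt[keep]
  for (a in c("cells", "provenance")) setattr(out, a, attr(table, a))
  setattr(out, "class", unique(c("variant_table", class(out))))
  out[]
}
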