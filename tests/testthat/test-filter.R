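# Database-labelled training sets and the SVM mutation filter.

toy_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    cell_id = sample(paste0("c", 1:5), n, replace = TRUE),
    chrom = "chrT", pos = seq_len(n) * 10L, ref = "A", alt = "G",
    depth = sample(5:40, n, replace = TRUE),
    alt_count = sample(2:5, n, replace = TRUE),
    vaf = runif(n, 0.1, 0.9),
    mean_base_qual = rnorm(n, 35, 2),
    strand_alt_fwd = 1L, strand_alt_rev = 1L,
    substitution_class = sample(c("C>T", "T>C", "C>A"), n, replace = TRUE),
    tri_context = "ACA", region_class = "exonic")
}

test_that("training labels follow the database rule", {
  tab <- toy_table()
  tab$substitution_class[5] <- "MBS"
  dbsnp <- data.table::data.table(chrom = "chrT", pos = c(10L, 20L),
                                  ref = "A", alt = "G", af = c(0.4, 0.001))
  editing <- data.table::data.table(chrom = "chrT", pos = c(30L, 40L),
                                    ref = "A", alt = "G",
                                    func = c("synonymous", "nonsynonymous"))
  ts <- build_training_set(tab, dbsnp, editing, common_af = 0.01)
  lab <- setNames(ts$label, ts$table$pos)
  expect_equal(unname(lab["10"]), "pos")       # common dbSNP record
  expect_true(is.na(lab["20"]))                # below common_af
  expect_equal(unname(lab["30"]), "neg")       # non-aa-changing editing site
  expect_true(is.na(lab["40"]))                # aa-changing editing excluded
  expect_equal(unname(lab["50"]), "neg")       # MBS call

  # both classes must be non-empty
  expect_error(build_training_set(toy_table(), dbsnp,
                                  editing[func == "nonsynonymous"]),
               "empty training class")
})

test_that("a linearly separable toy set is classified perfectly and deterministically", {
  set.seed(2)
  n <- 40
  tab <- toy_table(n)
  tab$vaf <- c(runif(n / 2, 0.6, 0.9), runif(n / 2, 0.05, 0.2))
  tab$alt_count <- round(tab$vaf * tab$depth)
  dbsnp <- data.table::data.table(chrom = "chrT", pos = seq_len(n / 2) * 10L,
                                  ref = "A", alt = "G", af = 0.5)
  editing <- data.table::data.table(chrom = "chrT",
                                    pos = (n / 2 + seq_len(n / 2)) * 10L,
                                    ref = "A", alt = "G", func = "unknown")
  ts <- build_training_set(tab, dbsnp, editing)
  m <- train_filter(ts, seed = 4)
  dv <- filter_decision(m, ts$table)
  expect_true(all(dv[ts$label == "pos"] > 0))
  expect_true(all(dv[ts$label == "neg"] < 0))
  expect_equal(m$cv_auroc, 1)
  # same seed, same decisions
  m2 <- train_filter(ts, seed = 4)
  expect_identical(filter_decision(m2, ts$table), dv)
  # training is invariant to row order
  perm <- sample(nrow(ts$table))
  # row order leaves the fitted boundary unchanged up to solver tolerance
  ts_perm <- build_training_set(tab[perm], dbsnp, editing)
  m3 <- train_filter(ts_perm, seed = 4)
  dv3 <- filter_decision(m3, ts$table)
  expect_equal(dv3, dv, tolerance = 1e-2)
  expect_identical(sign(dv3), sign(dv))
})

test_that("identical class distributions give chance-level AUROC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    tab <- toy_table(n, seed = s)
    half <- sample(n, n / 2)
    dbsnp <- data.table::data.table(chrom = "chrT", pos = tab$pos[half],
                                    ref = "A", alt = "G", af = 0.5)
    editing <- data.table::data.table(chrom = "chrT",
                                      pos = tab$pos[-half],
                                      ref = "A", alt = "G", func = "unknown")
    ts <- build_training_set(tab, dbsnp, editing)
    train_filter(ts, seed = s)$cv_auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 2 * sd(aucs) / sqrt(20) + 0.1)
})

test_that("filtering is monotone in the decision threshold", {
  sim <- small_bam_sim()
  calls <- call_variants(sim$bam, sim$fasta, barcode_policy = "tag")
  ts <- build_training_set(calls, sim$dbsnp_vcf, sim$editing_tsv)
  m <- train_filter(ts, seed = 1)
  kept_all <- score_and_filter(m, ts$table, decision_threshold = -Inf,
                               strict_svm = TRUE)
  kept_none <- score_and_filter(m, ts$table, decision_threshold = Inf,
                                strict_svm = TRUE)
  expect_equal(nrow(kept_all), nrow(ts$table))
  expect_equal(nrow(kept_none), 0)
  prev <- NULL
  for (thr in c(-2, -1, 0, 1, 2)) {
    kk <- score_and_filter(m, ts$table, decision_threshold = thr,
                           strict_svm = TRUE)
    keys <- paste(kk$cell_id, kk$site_key)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  # database positives are retained regardless under the default policy
  kept_db <- score_and_filter(m, ts$table, decision_threshold = Inf,
                              dbsnp_keys = ts$dbsnp_keys)
  expect_true(all(kept_db$site_key %in% ts$dbsnp_keys))
  expect_gt(nrow(kept_db), 0)
})

test_that("decision values match the sign of a hand-computed linear boundary", {
  # linear kernel, two clean clusters: w.x + b must separate them
  set.seed(6)
  n <- 30
  tab <- toy_table(n)
  tab$vaf <- c(rep(0.9, 15), rep(0.1, 15))
  tab$depth <- 20L
  tab$alt_count <- as.integer(tab$vaf * 20)
  dbsnp <- data.table::data.table(chrom = "chrT", pos = tab$pos[1:15],
                                  ref = "A", alt = "G", af = 0.5)
  editing <- data.table::data.table(chrom = "chrT", pos = tab$pos[16:30],
                                    ref = "A", alt = "G", func = "unknown")
  ts <- build_training_set(tab, dbsnp, editing)
  m <- train_filter(ts, kernel = "linear", seed = 1)
  dv <- filter_decision(m, ts$table)
  sv <- m$svm
  w <- t(sv$coefs) %*% sv$SV
  X <- call_features(ts$table, editing_sites = m$editing_sites)
  Xs <- scale(X[, m$features, drop = FALSE], m$center, m$scale)
  manual <- as.numeric(Xs %*% t(w)) - sv$rho
  if (m$flip) manual <- -manual
  expect_equal(sign(dv), sign(manual))
  expect_equal(dv, manual, tolerance = 1e-8)
})

test_that("schema mismatch is reported with the missing features", {
  tab <- toy_table()
  dbsnp <- data.table::data.table(chrom = "chrT", pos = tab$pos[1:20],
                                  ref = "A", alt = "G", af = 0.5)
  editing <- data.table::data.table(chrom = "chrT", pos = tab$pos[21:40],
                                    ref = "A", alt = "G", func = "unknown")
  ts <- build_training_set(tab, dbsnp, editing)
  m <- train_filter(ts, seed = 1)
  m$features <- c(m$features, "not_a_feature")
  expect_error(filter_decision(m, ts$table), "not_a_feature")
})
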