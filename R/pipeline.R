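## End-to-end pipeline: calls -> filter -> genotypes -> imputation ->
## denoising -> clones -> signatures [-> spatial], driven by a YAML config,
## with per-stage artifacts and a deterministic seed.

#' Default pipeline configuration
#' @return nested list of per-stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1,
    inputs = list(bam = NULL, bams = NULL, reference = NULL, gtf = NULL,
                  dbsnp = NULL, editing = NULL, annotations = NULL,
                  expression_clusters = NULL, positions = NULL),
    out_dir = "clonescope_out",
    stages = list(call = TRUE, filter = TRUE, genotype = TRUE,
                  impute = TRUE, denoise = TRUE, clones = TRUE,
                  signature = TRUE, spatial = FALSE),
    call = list(barcode_policy = "tag", tag = "CB", min_depth = 2,
                min_alt = 2, min_base_qual = 20, min_map_qual = 20),
    filter = list(common_af = 0.01, kernel = "radial", cost = 1,
                  decision_threshold = 0, strict_svm = FALSE),
    genotype = list(epsilon = 0.001, overdispersion = 100, confidence = 0.8,
                    min_sites = 10, imbalance = NULL),
    impute = list(dist_quantile = 0.15, min_overlap = 5, min_votes = 3,
                  same_type = FALSE, sig_floor = 0),
    denoise = list(lambda = NULL, sparse_cut = 0.5, min_cells = 3),
    clones = list(k_range = c(2, 10), gini_quantile = 0.75, n_trees = 500,
                  cv_folds = 5, complexity_penalty = 0),
    spatial = list(min_mutations = 20, min_group = 10))
}

.merge_config <- function(config) {
  base <- default_config()
  check_keys <- function(user, ref, path = "") {
    for (k in names(user)) {
      if (!(k %in% names(ref))) {
        stop("unknown config key: ", paste0(path, k))
      }
      if (is.list(ref[[k]]) && is.list(user[[k]]) && length(names(ref[[k]]))) {
        check_keys(user[[k]], ref[[k]], paste0(path, k, "."))
      }
    }
  }
  check_keys(config, base)
  utils::modifyList(base, config)
}

#' Run the full clonal-inference pipeline
#'
#' Executes the enabled stages in order, writing each stage's artifact plus
#' the resolved configuration and a log into `out_dir`. Disabled stages pass
#' the previous artifact through unchanged.
#'
#' @param config nested list (see [default_config()]) or a YAML file path.
#' @return list of class `pipeline_result` with the main artifacts:
#'   `calls`, `filtered`, `matrix`, `smoothed`, `denoised`, `assignment`,
#'   `signature_raw`, `signature_filtered`, `subclones`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), "|", ...,
                            "\n", file = log_path, append = TRUE)
  set.seed(cfg$seed)
  res <- list(out_dir = cfg$out_dir)

  src <- if (!is.null(cfg$inputs$bams)) cfg$inputs$bams else cfg$inputs$bam
  gm_model <- if (!is.null(cfg$inputs$gtf)) load_gene_model(cfg$inputs$gtf)

  ## call
  stopifnot(!is.null(src), !is.null(cfg$inputs$reference))
  calls <- call_variants(src, cfg$inputs$reference,
                         barcode_policy = cfg$call$barcode_policy,
                         gene_model = gm_model, tag = cfg$call$tag,
                         min_depth = cfg$call$min_depth,
                         min_alt = cfg$call$min_alt,
                         min_base_qual = cfg$call$min_base_qual,
                         min_map_qual = cfg$call$min_map_qual)
  fwrite(calls, file.path(cfg$out_dir, "calls_raw.tsv"), sep = "\t")
  logf("call:", nrow(calls), "raw calls across",
       length(attr(calls, "cells")), "cells")
  res$calls <- calls

  ## filter
  filtered <- calls
  model <- NULL
  if (isTRUE(cfg$stages$filter) && !is.null(cfg$inputs$dbsnp) &&
      !is.null(cfg$inputs$editing)) {
    ts <- build_training_set(calls, cfg$inputs$dbsnp, cfg$inputs$editing,
                             common_af = cfg$filter$common_af)
    model <- train_filter(ts, kernel = cfg$filter$kernel,
                          cost = cfg$filter$cost, seed = cfg$seed)
    filtered <- score_and_filter(model, ts$table,
                                 decision_threshold =
                                   cfg$filter$decision_threshold,
                                 dbsnp_keys = ts$dbsnp_keys,
                                 strict_svm = cfg$filter$strict_svm)
    model_card <- list(seed = cfg$seed, features = model$features,
                       cv_auroc = model$cv_auroc, n_pos = model$n_pos,
                       n_neg = model$n_neg)
    jsonlite::write_json(model_card,
                         file.path(cfg$out_dir, "filter_model.json"),
                         auto_unbox = TRUE, digits = NA)
    fwrite(filtered, file.path(cfg$out_dir, "calls_filtered.tsv"), sep = "\t")
    logf("filter:", nrow(filtered), "of", nrow(calls), "calls retained;",
         "CV AUROC", round(model$cv_auroc, 3))
  }
  res$filtered <- filtered
  res$filter_model <- model

  ## signatures (raw vs filtered spectra)
  if (isTRUE(cfg$stages$signature)) {
    res$signature_raw <- signature_96(calls, cfg$inputs$reference)
    res$signature_filtered <- signature_96(filtered, cfg$inputs$reference)
    fwrite(data.table(context = context_96_levels(),
                      raw = res$signature_raw$counts,
                      filtered = res$signature_filtered$counts),
           file.path(cfg$out_dir, "signature_96.tsv"), sep = "\t")
    logf("signature: raw-vs-filtered cosine ",
         round(signature_cosine(res$signature_raw, res$signature_filtered), 3))
  }

  ## genotype: re-tally counts for every cell at the filtered sites so that
  ## covered wild-type cells contribute genotype-0 evidence rather than
  ## appearing as drop-outs
  snv <- as.data.table(filtered)[nchar(ref) == 1 & nchar(alt) == 1]
  if (!("gene" %in% names(snv))) snv[, gene := NA_character_]
  usites <- unique(snv[, .(chrom, pos, ref, alt, gene)],
                   by = c("chrom", "pos", "ref", "alt"))
  counts <- site_counts(src, usites,
                        barcode_policy = cfg$call$barcode_policy,
                        tag = cfg$call$tag,
                        min_base_qual = cfg$call$min_base_qual,
                        min_map_qual = cfg$call$min_map_qual)
  counts <- merge(counts, usites[, c("chrom", "pos", "ref", "alt", "gene")],
                  by = c("chrom", "pos", "ref", "alt"), all.x = TRUE)
  imb <- if (!is.null(cfg$genotype$imbalance)) fread(cfg$genotype$imbalance)
  gm <- build_genotype_matrix(counts, imbalance = imb,
                              epsilon = cfg$genotype$epsilon,
                              overdispersion = cfg$genotype$overdispersion,
                              confidence = cfg$genotype$confidence,
                              min_sites = cfg$genotype$min_sites)
  write_genotype_matrix(gm, file.path(cfg$out_dir, "genotype_raw"))
  logf("genotype:", length(gm$cells), "cells x", nrow(gm$sites), "sites")
  res$matrix <- gm

  ## impute
  smoothed <- gm
  if (isTRUE(cfg$stages$impute)) {
    d0 <- manhattan_distances(gm, min_overlap = cfg$impute$min_overlap)
    ann <- if (!is.null(cfg$inputs$annotations)) fread(cfg$inputs$annotations)
    graph <- find_neighbors(d0, annotations = ann,
                            dist_quantile = cfg$impute$dist_quantile,
                            same_type = isTRUE(cfg$impute$same_type),
                            sig_floor = cfg$impute$sig_floor)
    smoothed <- impute_dropouts(gm, graph, min_votes = cfg$impute$min_votes)
    write_genotype_matrix(smoothed, file.path(cfg$out_dir, "genotype_smoothed"))
    logf("impute:", sum(attr(smoothed, "imputed")), "entries filled")
  }
  res$smoothed <- smoothed

  ## denoise
  denoised <- smoothed
  if (isTRUE(cfg$stages$denoise)) {
    denoised <- denoise_matrix(smoothed, lambda = cfg$denoise$lambda,
                               sparse_cut = cfg$denoise$sparse_cut)
    denoised <- drop_rare_sites(denoised, min_cells = cfg$denoise$min_cells)
    write_genotype_matrix(denoised, file.path(cfg$out_dir, "genotype_denoised"))
    logf("denoise: rank ", attr(denoised, "rpca")$rank, "; ",
         nrow(denoised$sites), " sites kept")
  }
  res$denoised <- denoised

  ## clones
  if (isTRUE(cfg$stages$clones)) {
    d <- manhattan_distances(denoised, min_overlap = cfg$impute$min_overlap)
    k_range <- seq(cfg$clones$k_range[1], cfg$clones$k_range[2])
    cand <- hierarchical_clones(d, k_range = k_range,
                                complexity_penalty =
                                  cfg$clones$complexity_penalty)
    final <- refine_clones(denoised, cand,
                           gini_quantile = cfg$clones$gini_quantile,
                           complexity_penalty = cfg$clones$complexity_penalty,
                           k_range = k_range, n_trees = cfg$clones$n_trees,
                           seed = cfg$seed, cv_folds = cfg$clones$cv_folds)
    fwrite(data.table(cell_id = names(final$labels), clone = final$labels),
           file.path(cfg$out_dir, "clones.tsv"), sep = "\t")
    fwrite(final$scores, file.path(cfg$out_dir, "mutation_scores.tsv"),
           sep = "\t")
    writeLines(clone_newick(final), file.path(cfg$out_dir, "clones.nwk"))
    logf("clones: k =", final$chosen_k, "| CV accuracy",
         round(final$cv_accuracy, 3))
    res$assignment <- final
  }

  ## spatial
  if (isTRUE(cfg$stages$spatial) && !is.null(cfg$inputs$expression_clusters)) {
    ecl <- fread(cfg$inputs$expression_clusters)
    ec <- setNames(as.character(ecl[[2]]), as.character(ecl[[1]]))
    labs <- setNames(paste0("clone", res$assignment$labels),
                     names(res$assignment$labels))
    sub <- intersect_clones_with_expression(labs, ec,
                                            min_group = cfg$spatial$min_group)
    fwrite(data.table(spot_id = names(sub), subclone = sub),
           file.path(cfg$out_dir, "subclones.tsv"), sep = "\t")
    logf("spatial:", length(unique(sub)), "subclones")
    res$subclones <- sub
  }

  jsonlite::write_json(list(stages = cfg$stages, seed = cfg$seed,
                            n_calls = nrow(calls),
                            n_filtered = nrow(filtered)),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(res) <- "pipeline_result"
  res
}

#' Persist a genotype matrix as plain-text layers
#'
#' Writes `genotype.tsv`, `ref_count.tsv`, `alt_count.tsv` plus `cells.tsv`
#' and `sites.tsv` under `prefix`.
#' @param gm a `genotype_matrix`.
#' @param prefix output directory.
#' @return invisibly, the directory.
#' @export
write_genotype_matrix <- function(gm, prefix) {
  dir.create(prefix, recursive = TRUE, showWarnings = FALSE)
  for (layer in c("genotype", "ref_count", "alt_count")) {
    fwrite(as.data.table(gm[[layer]], keep.rownames = "cell_id"),
           file.path(prefix, paste0(layer, ".tsv")), sep = "\t")
  }
  fwrite(data.table(cell_id = gm$cells), file.path(prefix, "cells.tsv"),
         sep = "\t")
  fwrite(gm$sites, file.path(prefix, "sites.tsv"), sep = "\t")
  invisible(prefix)
}

#' Read a genotype matrix written by [write_genotype_matrix()]
#' @param prefix directory written by [write_genotype_matrix()].
#' @return a `genotype_matrix`.
#' @export
read_genotype_matrix <- function(prefix) {
  rd <- function(layer) {
    dt <- fread(file.path(prefix, paste0(layer, ".tsv")))
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
    m
  }
  G <- rd("genotype")
  storage.mode(G) <- "integer"
  structure(list(genotype = G, ref_count = rd("ref_count"),
                 alt_count = rd("alt_count"),
                 cells = fread(file.path(prefix, "cells.tsv"))$cell_id,
                 sites = fread(file.path(prefix, "sites.tsv"))),
            class = "genotype_matrix")
}

#' Render the report figures from persisted pipeline artifacts
#'
#' Variant-cell heatmap (cells grouped by clone, mutations in stepwise
#' accumulation order), a clone-vs-annotation flow (Sankey-style) diagram,
#' VAF histograms and the 96-context signature bars, plus a small HTML
#' index. Every figure is drawn from the returned pipeline artifacts only.
#'
#' @param result a `pipeline_result`.
#' @param annotations optional data.frame (cell_id, cell_type) for the flow
#'   diagram; omitted with a note when absent.
#' @return invisibly, the paths of the written files.
#' @export
render_reports <- function(result, annotations = NULL) {
  out <- file.path(result$out_dir, "report")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  gm <- result$denoised
  asn <- result$assignment

  if (!is.null(asn)) {
    ord <- order_variant_cell_map(gm, asn)
    G <- gm$genotype[ord$cell_order, ord$site_order, drop = FALSE]
    df <- data.table(cell = rep(seq_len(nrow(G)), ncol(G)),
                     site = rep(seq_len(ncol(G)), each = nrow(G)),
                     genotype = factor(as.vector(G), levels = c(0, 1, 2)))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = cell, y = site,
                                          fill = genotype)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_manual(values = c(`0` = "#f0f0f0", `1` = "#fdae61",
                                            `2` = "#d7191c"),
                                 na.value = "white") +
      ggplot2::labs(x = "cells (grouped by clone)",
                    y = "mutations (accumulation order)") +
      ggplot2::theme_minimal()
    f <- file.path(out, "variant_cell_map.png")
    ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 120)
    paths <- c(paths, f)

    if (!is.null(annotations)) {
      ann <- setNames(as.character(annotations$cell_type),
                      as.character(annotations$cell_id))
      f2 <- file.path(out, "clone_flow.png")
      p2 <- .flow_plot(ann[names(asn$labels)],
                       paste0("clone", asn$labels))
      ggplot2::ggsave(f2, p2, width = 6, height = 5, dpi = 120)
      paths <- c(paths, f2)
    } else {
      .cs_log("no annotations: flow diagram omitted")
    }
  }

  if (!is.null(result$matrix)) {
    vh <- vaf_histogram(result$matrix)
    df <- data.table(mid = vh$raw$mids, count = vh$raw$counts)
    p3 <- ggplot2::ggplot(df, ggplot2::aes(mid, count)) +
      ggplot2::geom_col(width = 0.045, fill = "#2b8cbe") +
      ggplot2::labs(x = "raw VAF", y = "count") + ggplot2::theme_minimal()
    f3 <- file.path(out, "vaf_histogram.png")
    ggplot2::ggsave(f3, p3, width = 5, height = 4, dpi = 120)
    paths <- c(paths, f3)
  }

  for (nm in c("signature_raw", "signature_filtered")) {
    if (!is.null(result[[nm]]) && result[[nm]]$n > 0) {
      f4 <- file.path(out, paste0(nm, ".png"))
      ggplot2::ggsave(f4, plot_signature(result[[nm]], title = nm),
                      width = 9, height = 3, dpi = 120)
      paths <- c(paths, f4)
    }
  }

  idx <- file.path(out, "index.html")
  writeLines(c("<html><body><h1>clonescope report</h1>",
               sprintf('<div><h2>%s</h2><img src="%s" width="700"/></div>',
                       basename(paths), basename(paths)),
               "</body></html>"), idx)
  invisible(c(paths, idx))
}

# two-axis categorical flow (Sankey-style) diagram in plain ggplot
.flow_plot <- function(left, right) {
  dt <- data.table(left = left, right = right)[, .N, by = .(left, right)]
  setorder(dt, left, right)
  lt <- dt[, .(n = sum(N)), by = left][, `:=`(y1 = cumsum(n), y0 = cumsum(n) - n)]
  rt <- dt[, .(n = sum(N)), by = right][, `:=`(y1 = cumsum(n), y0 = cumsum(n) - n)]
  dt[, `:=`(ly0 = 0, ly1 = 0, ry0 = 0, ry1 = 0)]
  offl <- setNames(lt$y0, lt$left)
  offr <- setNames(rt$y0, rt$right)
  for (i in seq_len(nrow(dt))) {
    dt$ly0[i] <- offl[dt$left[i]]; dt$ly1[i] <- dt$ly0[i] + dt$N[i]
    offl[dt$left[i]] <- dt$ly1[i]
    dt$ry0[i] <- offr[dt$right[i]]; dt$ry1[i] <- dt$ry0[i] + dt$N[i]
    offr[dt$right[i]] <- dt$ry1[i]
  }
  ribbons <- dt[, {
    x <- c(0.1, 0.9, 0.9, 0.1)
    y <- c(ly0, ry0, ry1, ly1)
    .(x = x, y = y, grp = paste(left, right))
  }, by = .(left, right, N)]
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = ribbons,
                          ggplot2::aes(x = x, y = y, group = grp,
                                       fill = right), alpha = 0.6) +
    ggplot2::geom_rect(data = lt, ggplot2::aes(xmin = 0.02, xmax = 0.1,
                                               ymin = y0, ymax = y1),
                       fill = "grey35") +
    ggplot2::geom_rect(data = rt, ggplot2::aes(xmin = 0.9, xmax = 0.98,
                                               ymin = y0, ymax = y1),
                       fill = "grey35") +
    ggplot2::geom_text(data = lt, ggplot2::aes(x = 0.0, y = (y0 + y1) / 2,
                                               label = left), hjust = 1) +
    ggplot2::geom_text(data = rt, ggplot2::aes(x = 1.0, y = (y0 + y1) / 2,
                                               label = right), hjust = 0) +
    ggplot2::xlim(-0.3, 1.3) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "clone")
}

#' Matrix-level clonal benchmark
#'
#' Simulates the standard clonal population, runs genotyping, imputation,
#' denoising and clustering, and reports the adjusted Rand index against the
#' planted clone labels plus the silhouette of the true labels after each
#' stage.
#'
#' @param seed simulation seed.
#' @param params simulation parameters ([benchmark_params()]).
#' @param rf_seed random-forest seed.
#' @return list: `ari`, `silhouettes` (inferred/smoothed/denoised), `k`,
#'   `labels`, `truth`.
#' @export
run_matrix_benchmark <- function(seed = 1, params = benchmark_params(),
                                 rf_seed = 1) {
  sim <- simulate_clonal_population(params, seed = seed)
  gm <- build_genotype_matrix(sim$counts, min_sites = 5)
  truth <- sim$truth$clone[gm$cells]

  sil <- function(g) {
    d <- manhattan_distances(g, min_overlap = 3)
    .mean_silhouette(.complete_dist(d$d), truth)
  }
  s_inferred <- sil(gm)
  d0 <- manhattan_distances(gm, min_overlap = 3)
  graph <- find_neighbors(d0, dist_quantile = 0.15)
  smoothed <- impute_dropouts(gm, graph, min_votes = 3)
  s_smoothed <- sil(smoothed)
  denoised <- drop_rare_sites(denoise_matrix(smoothed), min_cells = 3)
  s_denoised <- sil(denoised)

  d <- manhattan_distances(denoised, min_overlap = 3)
  cand <- hierarchical_clones(d, k_range = 2:6)
  final <- refine_clones(denoised, cand, k_range = 2:6, seed = rf_seed)
  ari <- adjusted_rand_index(final$labels, truth)
  list(ari = ari,
       silhouettes = c(inferred = s_inferred, smoothed = s_smoothed,
                       denoised = s_denoised),
       k = final$chosen_k, labels = final$labels, truth = truth)
}

#' Read-level spike-in recovery benchmark
#'
#' Builds (or reuses) the synthetic benchmark BAM, then for each replicate
#' seed designs `n` spike-in mutations (VAF >= 0.3 at sites with coverage
#' >= 10), edits the reads, reruns calling and SVM filtering with default
#' parameters, and computes the fraction of designed mutations re-detected
#' and retained, per pyrimidine substitution category.
#'
#' @param out_dir working directory for the synthetic data.
#' @param n designed mutations per replicate.
#' @param replicate_seeds one seed per replicate.
#' @param sim_seed seed for the background BAM.
#' @param sim an existing `bam_sim` to reuse (optional).
#' @return list: `recovery` (replicates x 6 categories), `mean_by_category`,
#'   `overall_mean`, `sim`.
#' @export
run_spikein_benchmark <- function(out_dir = tempfile("spike"), n = 1000,
                                  replicate_seeds = 1:6, sim_seed = 1,
                                  sim = NULL) {
  if (is.null(sim)) {
    sim <- write_synthetic_bam(out_dir, seed = sim_seed)
  }
  gm_model <- load_gene_model(sim$gtf)
  cats <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  rec <- matrix(NA_real_, length(replicate_seeds), length(cats),
                dimnames = list(paste0("rep", replicate_seeds), cats))
  for (ri in seq_along(replicate_seeds)) {
    rs <- replicate_seeds[ri]
    des <- design_spike_in(sim, n = n, seed = rs)
    sp <- spike_in(sim$bam, des,
                   file.path(out_dir, sprintf("spiked_%d.bam", rs)),
                   seed = rs)
    calls <- call_variants(sp$bam, sim$fasta, barcode_policy = "tag",
                           gene_model = gm_model)
    ts <- build_training_set(calls, sim$dbsnp_vcf, sim$editing_tsv)
    model <- train_filter(ts, seed = rs)
    kept <- score_and_filter(model, ts$table, dbsnp_keys = ts$dbsnp_keys)
    kept_keys <- paste(kept$cell_id, kept$chrom, kept$pos, kept$alt)
    des_norm <- normalize_substitution(des$ref, des$alt,
                                       rep("NNN", nrow(des)))
    des_cat <- des_norm$sub
    hit <- paste(des$cell_id, des$chrom, des$pos, des$alt) %in% kept_keys
    for (cc in cats) {
      sel <- des_cat == cc
      if (any(sel)) rec[ri, cc] <- mean(hit[sel])
    }
    unlink(file.path(out_dir, sprintf("spiked_%d.bam", rs)))
    unlink(file.path(out_dir, sprintf("spiked_%d.bam.bai", rs)))
  }
  list(recovery = rec, mean_by_category = colMeans(rec, na.rm = TRUE),
       overall_mean = mean(rec, na.rm = TRUE), sim = sim)
}
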