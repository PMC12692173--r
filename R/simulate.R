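## Synthetic clonal populations: ground-truth genotype matrices, read-level
## BAMs with germline variants, RNA editing and multi-base artifacts, and
## spike-in designs for recovery benchmarking. Everything is generated in
## code so the full pipeline runs with no external data.

#' Default benchmark simulation parameters
#'
#' Three clones on a chain tree, 60 cells, 80 clonal sites, negative-binomial
#' depth (mean 15, dispersion 2), 30% drop-out, balanced allelic expression
#' (rho = 0.5), error rate 0.001, and RNA-editing contamination amounting to
#' ~20% of raw calls.
#'
#' @return named list of parameters accepted by
#'   [simulate_clonal_population()].
#' @export
benchmark_params <- function() {
  list(n_cells = 60, n_clones = 3, n_sites = 80,
       depth_mean = 15, depth_size = 2, dropout = 0.3,
       rho = 0.5, epsilon = 0.001, overdispersion = 100,
       hom_fraction = 0.15, editing_rate = 0.2,
       editing_vaf_shape = c(2, 8), contig = "chrS", contig_length = 1e5)
}

.nb_depth <- function(n, mean, size) rnbinom(n, mu = mean, size = size)

# beta-binomial draw with mean mu and concentration s
.rbetabinom <- function(n_draws, size, mu, s) {
  p <- rbeta(n_draws, mu * s, (1 - mu) * s)
  rbinom(n_draws, size, p)
}

#' Simulate a clonal population with ground truth
#'
#' Builds a chain clone tree (each clone carries all ancestral mutations plus
#' its own), assigns cells to clones, and draws per-(cell, site) read counts:
#' a site in a cell drops out with probability `dropout`; otherwise depth is
#' negative-binomial and the alternate count is beta-binomial with mean
#' `epsilon` / `rho` / `1 - epsilon` for true genotype 0/1/2. Cell-level
#' RNA-editing events (T>C or C>T classes) are added at extra sites so that
#' editing accounts for roughly `editing_rate` of raw alt-bearing calls,
#' each with a low editing fraction (`Beta(editing_vaf_shape)`).
#'
#' @param params list as from [benchmark_params()]; missing entries take the
#'   benchmark defaults.
#' @param seed RNG seed; the same seed reproduces the simulation exactly.
#' @return list of class `clone_sim`: `truth` (clone tree, per-cell clone,
#'   true genotypes, site table), `counts` (long data.table: cell_id, chrom,
#'   pos, ref, alt, gene, ref_count, alt_count, is_editing) and `params`.
#' @export
simulate_clonal_population <- function(params = benchmark_params(), seed = 1) {
  p <- utils::modifyList(benchmark_params(), params)
  stopifnot(p$n_clones >= 2, p$n_cells >= p$n_clones, p$n_sites >= p$n_clones)
  set.seed(seed)

  clones <- rep(seq_len(p$n_clones), length.out = p$n_cells)
  clones <- sort(clones)
  cells <- sprintf("CELL%03d", seq_len(p$n_cells))
  node <- rep(seq_len(p$n_clones), length.out = p$n_sites)  # site -> tree node
  node <- sort(node)
  zyg <- ifelse(runif(p$n_sites) < p$hom_fraction, 2L, 1L)

  # chain tree: clone c carries every site whose node <= c
  G_true <- outer(clones, node, ">=") * rep(zyg, each = p$n_cells)
  storage.mode(G_true) <- "integer"

  # site coordinates on the synthetic contig, paired with a virtual gene id
  all_pos <- sample.int(p$contig_length - 2, p$n_sites * 6) + 1L
  all_pos <- all_pos[!duplicated(all_pos %/% 3L)][seq_len(p$n_sites * 3)]
  pos <- sort(all_pos[seq_len(p$n_sites)])
  edit_pool <- all_pos[(p$n_sites + 1):(p$n_sites * 3)]
  ref <- sample(c("A", "C", "G", "T"), p$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  gene <- paste0("G", (seq_len(p$n_sites) - 1) %/% 4 + 1)

  sites <- data.table(chrom = p$contig, pos = pos, ref = ref, alt = alt,
                      gene = gene, node = node, zygosity = zyg,
                      is_editing = FALSE)
  sites[, site_key := .site_key(chrom, pos, ref, alt)]

  # observed counts at clonal sites
  nc <- p$n_cells * p$n_sites
  expressed <- runif(nc) >= p$dropout
  depth <- .nb_depth(nc, p$depth_mean, p$depth_size)
  depth[!expressed] <- 0L
  g_flat <- as.vector(G_true)
  mu <- c(p$epsilon, p$rho, 1 - p$epsilon)[g_flat + 1L]
  altc <- integer(nc)
  ok <- depth > 0
  altc[ok] <- .rbetabinom(sum(ok), depth[ok], mu[ok], p$overdispersion)

  counts <- data.table(
    cell_id = rep(cells, times = p$n_sites),
    site_idx = rep(seq_len(p$n_sites), each = p$n_cells),
    depth = depth, alt_count = altc)[depth > 0]
  counts <- cbind(counts,
                  sites[counts$site_idx,
                        .(chrom, pos, ref, alt, gene, is_editing)])
  counts[, ref_count := depth - alt_count]

  # RNA-editing contamination sized against the true alt-bearing calls
  n_true_calls <- counts[alt_count >= 2 & !is_editing, .N]
  n_events <- round(p$editing_rate / (1 - p$editing_rate) * n_true_calls / 0.5)
  edit_counts <- NULL
  if (n_events > 0) {
    n_esites <- max(1L, ceiling(n_events / 4))
    epos <- sort(sample(edit_pool, min(n_esites, length(edit_pool))))
    eref <- sample(c("A", "T", "C", "G"), length(epos), replace = TRUE,
                   prob = c(.4, .4, .1, .1))
    ealt <- c(A = "G", T = "C", C = "T", G = "A")[eref]  # A-to-I / C-to-U
    ev_site <- sample(seq_along(epos), n_events, replace = TRUE)
    ev_cell <- sample(cells, n_events, replace = TRUE)
    ev <- unique(data.table(cell_id = ev_cell, site = ev_site))
    ed <- .nb_depth(nrow(ev), p$depth_mean, p$depth_size)
    keep <- ed > 0
    ev <- ev[keep]; ed <- ed[keep]
    evaf <- rbeta(nrow(ev), p$editing_vaf_shape[1], p$editing_vaf_shape[2])
    ea <- rbinom(nrow(ev), ed, evaf)
    edit_counts <- data.table(
      cell_id = ev$cell_id, chrom = p$contig, pos = epos[ev$site],
      ref = unname(eref[ev$site]), alt = unname(ealt[ev$site]),
      gene = NA_character_, is_editing = TRUE,
      depth = ed, alt_count = ea, ref_count = ed - ea)
    esites <- data.table(chrom = p$contig, pos = epos, ref = unname(eref),
                         alt = unname(ealt), gene = NA_character_,
                         node = NA_integer_, zygosity = NA_integer_,
                         is_editing = TRUE)
    esites[, site_key := .site_key(chrom, pos, ref, alt)]
    sites <- rbind(sites, esites)
  }
  counts[, site_idx := NULL]
  if (!is.null(edit_counts)) {
    counts <- rbind(counts, edit_counts[alt_count > 0], fill = TRUE)
  }

  structure(list(
    truth = list(tree_parent = c(NA_integer_, seq_len(p$n_clones - 1)),
                 clone = setNames(clones, cells),
                 genotype = matrix(G_true, p$n_cells, p$n_sites,
                                   dimnames = list(cells,
                                                   sites[!(is_editing)]$site_key)),
                 sites = sites, cells = cells, seed = seed),
    counts = counts[], params = p),
    class = "clone_sim")
}

#' @export
print.clone_sim <- function(x, ...) {
  cat("clone_sim:", length(x$truth$cells), "cells,",
      sum(!x$truth$sites$is_editing), "clonal sites,",
      sum(x$truth$sites$is_editing), "editing sites, seed", x$truth$seed, "\n")
  invisible(x)
}

## ---- synthetic reference + annotation -------------------------------------

#' Synthetic reference genome and gene annotation
#'
#' A single uniform-composition contig carrying evenly spaced genes, each
#' with 5'UTR / exon / intron / exon / 3'UTR structure (the last gene is a
#' single-exon ncRNA), so region annotation is exercised end to end.
#'
#' @param out_dir directory to write `genome.fa` (+ index) and `genes.gtf`;
#'   `NULL` keeps everything in memory.
#' @param contig,contig_length contig name and size (bp).
#' @param n_genes,gene_length gene count and span.
#' @param seed RNG seed.
#' @return list with `genome` (character), `contig`, `contig_length`,
#'   `genes` and `features` data.tables, and (if written) `fasta`, `gtf`
#'   paths.
#' @export
make_synthetic_reference <- function(out_dir = NULL, contig = "chrS",
                                     contig_length = 1e5, n_genes = 20,
                                     gene_length = 1000, seed = 1) {
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
                  collapse = "")
  gap <- floor((contig_length - n_genes * gene_length) / (n_genes + 1))
  stopifnot(gap > 0)
  starts <- gap + (seq_len(n_genes) - 1) * (gene_length + gap) + 1L
  genes <- data.table(gene_id = paste0("G", seq_len(n_genes)),
                      start = starts, end = starts + gene_length - 1L,
                      biotype = c(rep("protein_coding", n_genes - 1), "lincRNA"))
  # per-gene internal layout (fractions of gene_length)
  seg <- function(s, fr) {
    b <- s + round(cumsum(c(0, fr)) * gene_length)
    data.table(start = head(b, -1) + c(0, rep(1, length(fr) - 1)),
               end = b[-1])
  }
  feats <- list()
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    if (g$biotype == "lincRNA") {
      feats[[i]] <- data.table(type = "exon", start = g$start, end = g$end,
                               gene_id = g$gene_id, biotype = g$biotype)
    } else {
      sg <- seg(g$start, c(0.10, 0.25, 0.20, 0.25, 0.20))
      feats[[i]] <- data.table(
        type = c("five_prime_utr", "exon", "intron", "exon", "three_prime_utr"),
        start = sg$start, end = sg$end, gene_id = g$gene_id,
        biotype = g$biotype)
    }
  }
  features <- rbindlist(feats)
  out <- list(genome = genome, contig = contig, contig_length = contig_length,
              genes = genes, features = features)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(genome, contig)), fasta)
    Rsamtools::indexFa(fasta)
    gtf <- file.path(out_dir, "genes.gtf")
    .write_gtf(features, genes, contig, gtf)
    out$fasta <- fasta
    out$gtf <- gtf
  }
  out
}

.write_gtf <- function(features, genes, contig, path) {
  gtf_type <- c(exon = "exon", intron = "intron",
                five_prime_utr = "five_prime_utr",
                three_prime_utr = "three_prime_utr")
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    rows <- c(rows, paste(contig, "synthetic", "gene", g$start, g$end, ".",
                          "+", ".", attr_g, sep = "\t"))
    f <- features[features$gene_id == g$gene_id & features$type != "intron"]
    # UTRs are also exonic sequence; emit exon rows covering them
    for (j in seq_len(nrow(f))) {
      rows <- c(rows, paste(contig, "synthetic", gtf_type[f$type[j]],
                            f$start[j], f$end[j], ".", "+", ".",
                            sprintf('%s transcript_id "%s.t1";', attr_g,
                                    g$gene_id),
                            sep = "\t"))
    }
  }
  writeLines(rows, path)
}

## ---- read-level simulation -------------------------------------------------

#' Default parameters for the read-level (BAM) benchmark
#' @return named list understood by [write_synthetic_bam()].
#' @export
bam_benchmark_params <- function() {
  list(n_cells = 48, n_clones = 3, n_clonal_sites = 80,
       n_germline_sites = 120, n_editing_sites = 100, n_mbs_sites = 25,
       n_genes = 20, gene_length = 1000, contig = "chrS",
       contig_length = 1e5, read_length = 80L,
       depth_mean = 15, depth_size = 2, gene_dropout = 0.2,
       rho = 0.5, epsilon = 0.001, error_rate = 0.001,
       editing_level_shape = c(1.5, 10), editing_intron_utr3_frac = 0.8,
       editing_c2u_frac = 0.1, editing_cluster_frac = 0.85,
       premrna_frac = 0.35,
       mbs_cell_fraction = 0.3, mbs_vaf = 0.35,
       germline_af_range = c(0.05, 0.5), hom_fraction = 0.3)
}

# place k distinct positions inside gene bodies, >= 2 bp apart from `used`;
# an explicit candidate `pool` overrides the gene-body default
.place_sites <- function(genes, k, used = integer(0), spacing = 2L,
                         pool = NULL) {
  if (is.null(pool)) {
    pool <- unlist(lapply(seq_len(nrow(genes)), function(i)
      seq(genes$start[i] + 2L, genes$end[i] - 2L)))
  }
  if (length(used)) {
    bad <- unique(as.vector(outer(used, -spacing:spacing, `+`)))
    pool <- setdiff(pool, bad)
  }
  # enforce spacing within the sample itself
  sel <- integer(0)
  cand <- sample(pool)
  for (x in cand) {
    if (length(sel) >= k) break
    if (!length(sel) || min(abs(sel - x)) > spacing) sel <- c(sel, x)
  }
  if (length(sel) < k) stop("could not place ", k, " sites with spacing")
  sort(sel)
}

#' Simulate a barcoded single-cell BAM with full ground truth
#'
#' Generates a synthetic reference and annotation, plants germline common
#' variants (shared by all cells; these populate the dbSNP-like resource),
#' clonal somatic mutations on a chain clone tree, recurrent RNA-editing
#' sites with low per-cell editing fractions (these populate the
#' editing-site resource), and adjacent double-substitution (MBS) artifacts.
#' Per cell and gene, expression drops out with probability `gene_dropout`,
#' otherwise uniform reads at negative-binomial coverage are emitted; each
#' read base carries the planted allele with the event's allele fraction and
#' uniform sequencing error elsewhere. Writes a coordinate-sorted, indexed
#' BAM with `CB` barcode tags plus FASTA/FAI, GTF, a dbSNP-like VCF, an
#' editing-site TSV, and ground-truth tables.
#'
#' @param out_dir output directory (created).
#' @param params list as from [bam_benchmark_params()].
#' @param seed RNG seed (byte-identical outputs for identical seeds).
#' @return list of class `bam_sim` with file paths (`bam`, `fasta`, `gtf`,
#'   `dbsnp_vcf`, `editing_tsv`, `truth_tsv`), the `reference` object,
#'   `sites` (all planted events), `clone` (per-cell labels), `cells` and
#'   `params`.
#' @export
write_synthetic_bam <- function(out_dir, params = bam_benchmark_params(),
                                seed = 1) {
  p <- utils::modifyList(bam_benchmark_params(), params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_synthetic_reference(out_dir, contig = p$contig,
                                  contig_length = p$contig_length,
                                  n_genes = p$n_genes,
                                  gene_length = p$gene_length, seed = seed)
  set.seed(seed + 1L)
  cells <- sprintf("CELL%03d", seq_len(p$n_cells))
  clones <- sort(rep(seq_len(p$n_clones), length.out = p$n_cells))
  genome <- strsplit(ref$genome, "")[[1]]

  ## --- site design ----------------------------------------------------------
  pos_all <- .place_sites(ref$genes,
                          p$n_clonal_sites + p$n_germline_sites +
                            p$n_mbs_sites, spacing = 2L)
  idx <- seq_along(pos_all)
  take <- function(k) {
    sel <- sample(idx, k); idx <<- setdiff(idx, sel); sort(pos_all[sel])
  }
  pos_clonal <- take(p$n_clonal_sites)
  pos_germ <- take(p$n_germline_sites)
  pos_mbs <- take(p$n_mbs_sites)        # MBS occupies pos and pos + 1
  # A-to-I editing is Alu-driven: overwhelmingly in introns/3'UTRs and at
  # A/T reference bases (a ~10% minority of C-to-U events at C/G bases)
  iu_pool <- ref$features[ref$features$type %in% c("intron",
                                                   "three_prime_utr")]
  iu_pool <- unlist(lapply(seq_len(nrow(iu_pool)), function(i)
    seq(iu_pool$start[i], iu_pool$end[i])))
  gene_pool <- unlist(lapply(seq_len(nrow(ref$genes)), function(i)
    seq(ref$genes$start[i] + 2L, ref$genes$end[i] - 2L)))
  at_pool <- which(genome %in% c("A", "T"))
  cg_pool <- which(genome %in% c("C", "G"))
  # most A-to-I sites sit in clusters (inverted Alu repeats); a minority are
  # scattered singletons, including the C-to-U events
  n_clustered <- round(p$editing_cluster_frac * p$n_editing_sites)
  sites_per_cluster <- 6L
  n_clusters <- max(1L, round(n_clustered / sites_per_cluster))
  center_pool <- setdiff(intersect(iu_pool, at_pool),
                         as.vector(outer(pos_all, -2:2, `+`)))
  centers <- integer(0)
  for (x in sample(center_pool)) {    # centers well separated from each other
    if (length(centers) >= n_clusters) break
    if (!length(centers) || min(abs(centers - x)) > 150L) {
      centers <- c(centers, x)
    }
  }
  if (length(centers) < n_clusters) {
    stop("could not place ", n_clusters, " editing cluster centers")
  }
  pos_edit <- integer(0)
  for (ct in centers) {
    cand <- intersect((ct - 60L):(ct + 60L), intersect(gene_pool, at_pool))
    cand <- setdiff(cand, as.vector(outer(c(pos_all, pos_edit), -2:2, `+`)))
    sel <- integer(0)
    for (x in sample(cand)) {
      if (length(sel) >= sites_per_cluster) break
      if (!length(sel) || min(abs(sel - x)) > 3L) sel <- c(sel, x)
    }
    pos_edit <- c(pos_edit, sel)
  }
  n_single <- p$n_editing_sites - length(pos_edit)
  n_cu <- min(n_single, round(p$editing_c2u_frac * p$n_editing_sites))
  if (n_single - n_cu > 0) {
    pos_edit <- c(pos_edit,
                  .place_sites(ref$genes, n_single - n_cu,
                               used = c(pos_all, pos_edit),
                               pool = intersect(gene_pool, at_pool)))
  }
  if (n_cu > 0) {
    pos_edit <- c(pos_edit,
                  .place_sites(ref$genes, n_cu, used = c(pos_all, pos_edit),
                               pool = intersect(gene_pool, cg_pool)))
  }
  pos_edit <- sort(pos_edit)

  # germline and somatic variation is transition-biased (Ts:Tv ~ 2:1)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  rand_alt <- function(r, ts_bias = 2 / 3) vapply(r, function(b) {
    if (runif(1) < ts_bias) transition[[b]]
    else sample(setdiff(c("A", "C", "G", "T"), c(b, transition[[b]])), 1)
  }, character(1))

  node <- sort(rep(seq_len(p$n_clones), length.out = p$n_clonal_sites))
  clonal <- data.table(kind = "clonal", chrom = p$contig, pos = pos_clonal,
                       ref = genome[pos_clonal],
                       alt = rand_alt(genome[pos_clonal]),
                       node = node,
                       zygosity = ifelse(runif(p$n_clonal_sites) < 0.15, 2L, 1L))
  germ <- data.table(kind = "germline", chrom = p$contig, pos = pos_germ,
                     ref = genome[pos_germ], alt = rand_alt(genome[pos_germ]),
                     node = NA_integer_,
                     zygosity = ifelse(runif(p$n_germline_sites) <
                                         p$hom_fraction, 2L, 1L))
  # editing: A-to-I (A>G / T>C) with a minority of C-to-U (C>T / G>A)
  eref <- genome[pos_edit]
  ealt <- c(A = "G", T = "C", C = "T", G = "A")[eref]
  edit <- data.table(kind = "editing", chrom = p$contig, pos = pos_edit,
                     ref = eref, alt = unname(ealt), node = NA_integer_,
                     zygosity = NA_integer_)
  mbs <- data.table(kind = "mbs", chrom = p$contig, pos = pos_mbs,
                    ref = genome[pos_mbs], alt = rand_alt(genome[pos_mbs]),
                    node = NA_integer_, zygosity = NA_integer_)
  mbs2 <- data.table(kind = "mbs", chrom = p$contig, pos = pos_mbs + 1L,
                     ref = genome[pos_mbs + 1L],
                     alt = rand_alt(genome[pos_mbs + 1L]),
                     node = NA_integer_, zygosity = NA_integer_)
  mbs_cells <- lapply(seq_len(p$n_mbs_sites), function(i)
    sample(cells, max(2, round(p$mbs_cell_fraction * p$n_cells))))
  sites <- rbind(clonal, germ, edit, mbs, mbs2)
  setorder(sites, pos)

  ## --- per-(cell, site) alternate-allele fraction ---------------------------
  # list: pos -> function(cell) -> expected alt fraction
  vaf_map <- new.env(parent = emptyenv())
  het_mu <- function(z) ifelse(z == 2L, 1 - p$epsilon, p$rho)
  for (i in seq_len(nrow(clonal))) {
    carriers <- cells[clones >= clonal$node[i]]
    mu <- het_mu(clonal$zygosity[i])
    assign(as.character(clonal$pos[i]),
           list(cells = carriers, mu = mu, alt = clonal$alt[i]), vaf_map)
  }
  for (i in seq_len(nrow(germ))) {
    assign(as.character(germ$pos[i]),
           list(cells = cells, mu = het_mu(germ$zygosity[i]),
                alt = germ$alt[i]), vaf_map)
  }
  # editing level is a site property: every cell expressing the gene edits
  # a low (beta-distributed) fraction of its transcripts at the site
  edit_level <- rbeta(nrow(edit), p$editing_level_shape[1],
                      p$editing_level_shape[2])
  for (i in seq_len(nrow(edit))) {
    assign(as.character(edit$pos[i]),
           list(cells = cells, mu = edit_level[i], alt = edit$alt[i]),
           vaf_map)
  }
  for (i in seq_len(p$n_mbs_sites)) {
    # both positions substituted on the same read (true doublet artifact)
    assign(as.character(pos_mbs[i]),
           list(cells = mbs_cells[[i]], mu = p$mbs_vaf,
                alt = mbs$alt[i], pair_alt = mbs2$alt[i], mbs = TRUE),
           vaf_map)
  }

  ## --- reads ----------------------------------------------------------------
  ## Coverage is split into a pre-mRNA layer (uniform across the gene body,
  ## including introns) and a mature-transcript layer confined to exonic
  ## segments, so intronic coverage is a minority of exonic coverage as in
  ## real RNA-seq.
  rl <- as.integer(p$read_length)
  exonic_segs <- ref$features[ref$features$type != "intron"]
  sam_body <- vector("list", p$n_cells)
  read_counter <- 0L
  site_pos <- sites$pos
  for (ci in seq_len(p$n_cells)) {
    cell_rows <- list()
    for (gi in seq_len(nrow(ref$genes))) {
      if (runif(1) < p$gene_dropout) next
      d <- .nb_depth(1, p$depth_mean, p$depth_size)
      if (d == 0) next
      g <- ref$genes[gi]
      n_reads <- max(1L, round(d * (g$end - g$start + 1) / rl))
      n_pre <- round(p$premrna_frac * n_reads)
      starts_pre <- sample(seq(g$start, max(g$start, g$end - rl + 1L)),
                           n_pre, replace = TRUE)
      segs <- exonic_segs[exonic_segs$gene_id == g$gene_id &
                            (exonic_segs$end - exonic_segs$start + 1L) >= rl]
      if (nrow(segs)) {
        wts <- segs$end - segs$start - rl + 2L
        pick <- sample.int(nrow(segs), n_reads - n_pre, replace = TRUE,
                           prob = wts)
        starts_mat <- segs$start[pick] +
          floor(runif(n_reads - n_pre) * wts[pick])
      } else {
        starts_mat <- sample(seq(g$start, max(g$start, g$end - rl + 1L)),
                             n_reads - n_pre, replace = TRUE)
      }
      starts <- c(starts_pre, as.integer(starts_mat))
      n_reads <- length(starts)
      seqs <- substring(ref$genome, starts, starts + rl - 1L)
      mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                    nrow = n_reads, byrow = TRUE)
      # sequencing error: uniform substitution
      n_err <- rbinom(1, n_reads * rl, p$error_rate)
      if (n_err > 0) {
        at <- sample.int(n_reads * rl, n_err)
        mat[at] <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
      }
      # planted alleles at sites covered by this gene's reads
      in_gene <- site_pos[site_pos >= g$start & site_pos <= g$end]
      for (sp in in_gene) {
        ev <- get0(as.character(sp), envir = vaf_map)
        if (is.null(ev) || !(cells[ci] %in% ev$cells)) next
        mu <- if (length(ev$mu) > 1) ev$mu[[cells[ci]]] else ev$mu
        covering <- which(starts <= sp & starts + rl - 1L >= sp)
        if (!length(covering)) next
        carry <- covering[runif(length(covering)) < mu]
        if (!length(carry)) next
        off <- sp - starts[carry] + 1L
        mat[cbind(carry, off)] <- ev$alt
        if (isTRUE(ev$mbs)) {
          off2 <- off + 1L
          okc <- off2 <= rl
          if (any(okc)) mat[cbind(carry[okc], off2[okc])] <- ev$pair_alt
        }
      }
      seqs <- apply(mat, 1, paste, collapse = "")
      q <- pmin(pmax(round(rnorm(n_reads * rl, 35, 3)), 25), 40)
      quals <- vapply(seq_len(n_reads), function(r)
        rawToChar(as.raw(q[((r - 1) * rl + 1):(r * rl)] + 33L)),
        character(1))
      flags <- ifelse(runif(n_reads) < 0.5, 0L, 16L)
      qn <- sprintf("r%08d", read_counter + seq_len(n_reads))
      read_counter <- read_counter + n_reads
      cell_rows[[gi]] <- paste(qn, flags, p$contig, starts, 60L,
                               paste0(rl, "M"), "*", 0L, 0L, seqs, quals,
                               paste0("CB:Z:", cells[ci]), sep = "\t")
    }
    sam_body[[ci]] <- unlist(cell_rows)
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", p$contig, as.integer(p$contig_length)))
  sam_path <- file.path(out_dir, "reads.sam")
  writeLines(c(header, unlist(sam_body)), sam_path)
  bam <- Rsamtools::asBam(sam_path, file.path(out_dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)

  ## --- resources + truth ----------------------------------------------------
  dbsnp <- file.path(out_dir, "dbsnp.vcf")
  af <- round(runif(nrow(germ), p$germline_af_range[1],
                    p$germline_af_range[2]), 4)
  .write_simple_vcf(dbsnp, germ$chrom, germ$pos, germ$ref, germ$alt,
                    info = sprintf("AF=%s", af),
                    contig = p$contig, contig_length = p$contig_length)
  editing_tsv <- file.path(out_dir, "editing_sites.tsv")
  fwrite(data.table(chrom = edit$chrom, pos = edit$pos, ref = edit$ref,
                    alt = edit$alt,
                    func = sample(c("synonymous", "intronic", "UTR3",
                                    "unknown"),
                                  nrow(edit), replace = TRUE)),
         editing_tsv, sep = "\t")
  truth_tsv <- file.path(out_dir, "truth_sites.tsv")
  fwrite(sites, truth_tsv, sep = "\t")
  clone_tsv <- file.path(out_dir, "truth_clones.tsv")
  fwrite(data.table(cell_id = cells, clone = clones), clone_tsv, sep = "\t")

  structure(list(bam = bam, fasta = ref$fasta, gtf = ref$gtf,
                 dbsnp_vcf = dbsnp, editing_tsv = editing_tsv,
                 truth_tsv = truth_tsv, clone_tsv = clone_tsv,
                 reference = ref, sites = sites,
                 clone = setNames(clones, cells), cells = cells,
                 params = p, seed = seed),
            class = "bam_sim")
}

.write_simple_vcf <- function(path, chrom, pos, ref, alt, info = ".",
                              contig = NULL, contig_length = NULL,
                              extra_header = character(0)) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig))
             sprintf("##contig=<ID=%s,length=%d>", contig,
                     as.integer(contig_length)),
           '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
           extra_header,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  o <- order(chrom, pos)
  body <- paste(chrom[o], pos[o], ".", ref[o], alt[o], ".", "PASS",
                rep_len(info, length(chrom))[o], sep = "\t")
  writeLines(c(hdr, body), path)
}

## ---- spike-in ---------------------------------------------------------------

#' Design a spike-in experiment against an existing BAM
#'
#' Picks `n` (cell, position) pairs not overlapping any planted site, with
#' per-cell coverage of at least `min_cov`, assigns a random alternate base
#' and a genotype-consistent designed VAF: a mutation in a single diploid
#' cell is heterozygous (VAF 0.5) or homozygous (VAF 1), mixed at
#' `hom_fraction`.
#'
#' @param sim a `bam_sim` object (or list with `bam`, `reference`, `sites`).
#' @param n number of designed mutations.
#' @param seed RNG seed.
#' @param min_cov minimum per-cell read coverage at the chosen site.
#' @param hom_fraction fraction of designs at homozygous VAF 1.
#' @return data.table with columns cell_id, chrom, pos, ref, alt, vaf.
#' @export
design_spike_in <- function(sim, n = 1000, seed = 1, min_cov = 10,
                            hom_fraction = 0.15) {
  set.seed(seed)
  streams <- demux_cells(sim$bam, barcode_policy = "tag")
  genome <- strsplit(sim$reference$genome, "")[[1]]
  used <- sim$sites$pos
  bad <- unique(as.vector(outer(used, -2:2, `+`)))
  cand <- list()
  for (cc in names(streams$reads)) {
    cov <- .coverage_table(streams$reads[[cc]])
    cov <- cov[count >= min_cov & !(pos %in% bad)]
    if (nrow(cov)) cand[[cc]] <- data.table(cell_id = cc, pos = cov$pos)
  }
  cand <- rbindlist(cand)
  if (nrow(cand) < n) stop("not enough covered candidate sites for spike-in")
  # one designed mutation per genomic position (sites absent from background)
  cand <- cand[sample.int(nrow(cand))]
  cand <- cand[!duplicated(pos)]
  # avoid adjacent designed sites (would merge into MBS calls): greedy
  # thinning keeps positions > 2 bp from the last kept one
  setorder(cand, pos)
  keepr <- logical(nrow(cand))
  last <- -10L
  for (i in seq_len(nrow(cand))) {
    if (cand$pos[i] - last > 2L) { keepr[i] <- TRUE; last <- cand$pos[i] }
  }
  cand <- cand[keepr]
  if (nrow(cand) < n) stop("not enough spaced candidate sites for spike-in")
  des <- cand[sort(sample.int(nrow(cand), n))]
  des[, ref := genome[pos]]
  des[, alt := vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))]
  des[, vaf := ifelse(runif(n) < hom_fraction, 1, 0.5)]
  des[, chrom := sim$params$contig]
  des[, .(cell_id, chrom, pos, ref, alt, vaf)]
}

# per-cell coverage from a read table (all-M fast path)
.coverage_table <- function(reads) {
  w <- .cigar_ref_width(reads$cigar)
  dt <- data.table(pos = unlist(lapply(seq_len(nrow(reads)), function(i)
    seq.int(reads$pos[i], reads$pos[i] + w[i] - 1L))))
  dt[, .(count = .N), by = pos]
}

#' Introduce designed mutations into a BAM by read editing
#'
#' For each designed (cell, site, VAF): among that cell's reads covering the
#' site, `round(VAF * coverage)` reads (chosen at random under `seed`) have
#' their base at the site set to the designed alternate allele. All other
#' reads, read names, positions and qualities are untouched.
#'
#' @param bam input BAM path (barcoded, `CB` tags).
#' @param design data.table from [design_spike_in()].
#' @param out_bam output BAM path (sorted + indexed).
#' @param seed RNG seed for read selection.
#' @return list with `bam` (path) and `design` (with an `n_edited` column).
#' @export
spike_in <- function(bam, design, out_bam, seed = 1) {
  set.seed(seed)
  tmp_sam <- tempfile(fileext = ".sam")
  Rsamtools::asSam(bam, sub("\\.sam$", "", tmp_sam), overwrite = TRUE)
  lines <- readLines(tmp_sam)
  is_hdr <- startsWith(lines, "@")
  body <- lines[!is_hdr]
  f <- strsplit(body, "\t", fixed = TRUE)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  cig <- vapply(f, `[`, character(1), 6)
  cb <- vapply(f, function(x) {
    t <- grep("^CB:Z:", x, value = TRUE)
    if (length(t)) substring(t[1], 6) else NA_character_
  }, character(1))
  w <- .cigar_ref_width(cig)
  design <- as.data.table(copy(design))
  design[, n_edited := 0L]
  for (i in seq_len(nrow(design))) {
    d <- design[i]
    cov <- which(cb == d$cell_id & pos <= d$pos & pos + w - 1L >= d$pos &
                   grepl("^[0-9]+M$", cig))
    if (!length(cov)) next
    k <- max(1L, round(d$vaf * length(cov)))
    pick <- cov[sample.int(length(cov), min(k, length(cov)))]
    for (r in pick) {
      off <- d$pos - pos[r] + 1L
      s <- f[[r]][10]
      substr(s, off, off) <- d$alt
      f[[r]][10] <- s
    }
    design[i, n_edited := length(pick)]
  }
  body2 <- vapply(f, paste, character(1), collapse = "\t")
  out_sam <- tempfile(fileext = ".sam")
  writeLines(c(lines[is_hdr], body2), out_sam)
  res <- Rsamtools::asBam(out_sam, sub("\\.bam$", "", out_bam),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(c(tmp_sam, out_sam))
  list(bam = res, design = design[])
}
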