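# Synthetic fixtures: clonal population simulator, read-level BAMs and
# spike-in editing.

test_that("identical seeds reproduce the simulation exactly", {
  a <- simulate_clonal_population(seed = 5)
  b <- simulate_clonal_population(seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$genotype, b$truth$genotype)
  c2 <- simulate_clonal_population(seed = 6)
  expect_false(identical(a$counts, c2$counts))
})

test_that("clone tree mutation sets are nested along the chain", {
  sim <- simulate_clonal_population(seed = 2)
  G <- sim$truth$genotype
  cl <- sim$truth$clone
  for (k in 2:max(cl)) {
    anc <- colMeans(G[cl == k - 1, , drop = FALSE] > 0) == 1
    des <- colMeans(G[cl == k, , drop = FALSE] > 0) == 1
    expect_true(all(des[anc]))         # descendants keep ancestral mutations
    expect_gt(sum(des), sum(anc))      # and add their own
  }
})

test_that("limit parameters behave: no drop-out recovers truth, full drop-out empties", {
  full <- simulate_clonal_population(params = list(dropout = 0), seed = 3)
  cts <- full$counts[is_editing == FALSE]
  # every pair observed except negative-binomial zero-depth draws (~2%)
  expect_gt(nrow(cts), 0.95 * 60 * 80)
  none <- simulate_clonal_population(params = list(dropout = 1), seed = 3)
  expect_equal(nrow(none$counts[is_editing == FALSE]), 0)
})

test_that("editing contamination is sized near the requested fraction of raw calls", {
  sim <- simulate_clonal_population(seed = 4)
  calls <- sim$counts[alt_count >= 2]
  frac <- mean(calls$is_editing)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
})

test_that("truth marginals are stable across seeds while draws differ", {
  a <- simulate_clonal_population(seed = 11)
  b <- simulate_clonal_population(seed = 12)
  expect_false(identical(a$counts$alt_count, b$counts$alt_count))
  ma <- mean(a$counts[is_editing == FALSE]$depth)
  mb <- mean(b$counts[is_editing == FALSE]$depth)
  expect_lt(abs(ma - mb) / ma, 0.1)
  # identical clone structure by construction
  expect_identical(a$truth$clone, b$truth$clone)
})

test_that("synthetic BAM round-trips through the pileup caller", {
  sim <- small_bam_sim()
  expect_true(file.exists(sim$bam))
  expect_true(file.exists(paste0(sim$fasta, ".fai")))
  calls <- call_variants(sim$bam, sim$fasta, barcode_policy = "tag")
  expect_setequal(unique(calls$cell_id), sim$cells)
  # germline het sites: recovered depth and allele fraction near rho
  germ <- sim$sites[sim$sites$kind == "germline"]
  hits <- calls[paste(calls$pos, calls$alt) %in%
                  paste(germ$pos, germ$alt)]
  expect_gt(nrow(hits), 50)
  het_pos <- germ$pos[germ$zygosity == 1L]
  het_hits <- hits[hits$pos %in% het_pos]
  expect_lt(abs(median(het_hits$vaf) - 0.5), 0.12)
  hom_hits <- hits[!(hits$pos %in% het_pos)]
  expect_gt(median(hom_hits$vaf), 0.9)
})

test_that("same seed gives byte-identical synthetic BAMs", {
  d1 <- file.path(tempdir(), "sim_rep1")
  d2 <- file.path(tempdir(), "sim_rep2")
  p <- list(n_cells = 4, n_clones = 2, n_clonal_sites = 10,
            n_germline_sites = 10, n_editing_sites = 10, n_mbs_sites = 3,
            n_genes = 4, gene_length = 600, contig_length = 1e4)
  s1 <- write_synthetic_bam(d1, params = p, seed = 3)
  s2 <- write_synthetic_bam(d2, params = p, seed = 3)
  expect_identical(tools::md5sum(s1$bam)[[1]], tools::md5sum(s2$bam)[[1]])
  expect_identical(readLines(s1$dbsnp_vcf), readLines(s2$dbsnp_vcf))
})

test_that("spike-in edits exactly the designed alleles and nothing else", {
  sim <- small_bam_sim()
  des <- design_spike_in(sim, n = 25, seed = 2, min_cov = 8)
  expect_equal(nrow(des), 25)
  expect_true(all(des$vaf >= 0.3))
  expect_false(any(des$pos %in% sim$sites$pos))
  out <- file.path(tempdir(), "spiked_small.bam")
  sp <- spike_in(sim$bam, des, out, seed = 2)
  # read count, names and positions unchanged
  p0 <- Rsamtools::ScanBamParam(what = c("qname", "pos", "cigar", "qual"))
  a <- Rsamtools::scanBam(sim$bam, param = p0)[[1]]
  b <- Rsamtools::scanBam(sp$bam, param = p0)[[1]]
  expect_identical(sort(a$qname), sort(b$qname))
  expect_identical(a$pos[order(a$qname)], b$pos[order(b$qname)])
  expect_identical(as.character(a$qual)[order(a$qname)],
                   as.character(b$qual)[order(b$qname)])
  # designed mutations now visible to the caller in the right cells
  calls <- call_variants(sp$bam, sim$fasta, barcode_policy = "tag",
                         min_alt = 2)
  found <- paste(des$cell_id, des$pos, des$alt) %in%
    paste(calls$cell_id, calls$pos, calls$alt)
  expect_gt(mean(found), 0.9)
  # n = 0 design leaves alignments identical
  sp0 <- spike_in(sim$bam, des[0], file.path(tempdir(), "spiked0.bam"),
                  seed = 1)
  s_a <- Rsamtools::scanBam(sim$bam)[[1]]
  s_b <- Rsamtools::scanBam(sp0$bam)[[1]]
  expect_identical(as.character(s_a$seq), as.character(s_b$seq))
})

test_that("designed VAF 0.5 at even coverage edits half the covering reads", {
  genome <- paste(rep("ACGTGGTCA", 120), collapse = "")
  fa <- write_test_fasta(genome, contig = "chrT")
  reads <- lapply(1:20, function(i)
    list(qname = paste0("r", i), pos = 81L, seq = substr(genome, 81, 160),
         cb = "C1"))
  bam <- write_test_bam(reads, contig = "chrT", contig_len = nchar(genome))
  des <- data.table::data.table(cell_id = "C1", chrom = "chrT", pos = 120L,
                                ref = substr(genome, 120, 120), alt = "T",
                                vaf = 0.5)
  sp <- spike_in(bam, des, file.path(tempdir(), "half.bam"), seed = 1)
  expect_equal(sp$design$n_edited, 10L)
  st <- demux_cells(sp$bam, barcode_policy = "tag")
  calls <- pileup_call(st$reads$C1, fa)
  expect_equal(calls[calls$pos == 120L]$alt_count, 10L)
  expect_equal(calls[calls$pos == 120L]$depth, 20L)
})
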