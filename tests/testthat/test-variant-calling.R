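# Demultiplexing, pileup calling and region annotation on hand-built
# alignments with known base-by-base layouts.

make_toy_reference <- function() {
  # deterministic 1 kb sequence
  set.seed(99)
  paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
}

test_that("barcoded reads partition exactly by tag and untagged reads are discarded", {
  genome <- make_toy_reference()
  reads <- c(
    lapply(1:10, function(i) list(qname = paste0("a", i), pos = 100L + i,
                                  seq = substr(genome, 100 + i, 139 + i),
                                  cb = "BC1")),
    lapply(1:10, function(i) list(qname = paste0("b", i), pos = 300L + i,
                                  seq = substr(genome, 300 + i, 339 + i),
                                  cb = "BC2")),
    list(list(qname = "naked", pos = 500L,
              seq = substr(genome, 500, 539))))
  bam <- write_test_bam(reads)
  st <- demux_cells(bam, barcode_policy = "tag")
  expect_setequal(names(st$reads), c("BC1", "BC2"))
  expect_equal(nrow(st$reads$BC1), 10)
  expect_equal(nrow(st$reads$BC2), 10)
  expect_equal(st$discarded, 1L)
})

test_that("per-file policy names cells from file stems", {
  genome <- make_toy_reference()
  mk <- function(stem) write_test_bam(
    lapply(1:5, function(i) list(qname = paste0(stem, i), pos = 10L * i,
                                 seq = substr(genome, 10 * i, 10 * i + 39))),
    path = file.path(tempdir(), stem))
  bams <- c(mk("cellA"), mk("cellB"), mk("cellC"))
  st <- demux_cells(bams, barcode_policy = "per_file")
  expect_setequal(names(st$reads), c("cellA", "cellB", "cellC"))
  expect_error(demux_cells(character(0)), "empty")
})

test_that("pileup counts equal the hand-constructed read layout", {
  genome <- make_toy_reference()
  fa <- write_test_fasta(genome)
  ref_base <- substr(genome, 120, 120)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  # 10 reads over pos 101..160; 2 carry alt at 120 (one per strand), 8 ref
  reads <- lapply(1:10, function(i) {
    s <- substr(genome, 101, 160)
    if (i <= 2) substr(s, 20, 20) <- alt_base
    list(qname = paste0("r", i), pos = 101L, seq = s, cb = "BC1",
         flag = if (i %% 2) 0L else 16L)
  })
  bam <- write_test_bam(reads)
  st <- demux_cells(bam, barcode_policy = "tag")
  calls <- pileup_call(st$reads$BC1, fa, min_depth = 2, min_alt = 2)
  hit <- calls[calls$pos == 120L & calls$alt == alt_base]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$depth, 10L)
  expect_equal(hit$alt_count, 2L)
  expect_equal(hit$vaf, 0.2)
  expect_equal(hit$strand_alt_fwd + hit$strand_alt_rev, hit$alt_count)
  # no other positions reach min_alt
  expect_equal(nrow(calls), 1)

  # all reads alt: vaf 1
  reads2 <- lapply(1:10, function(i) {
    s <- substr(genome, 101, 160)
    substr(s, 20, 20) <- alt_base
    list(qname = paste0("r", i), pos = 101L, seq = s, cb = "BC1")
  })
  st2 <- demux_cells(write_test_bam(reads2), barcode_policy = "tag")
  c2 <- pileup_call(st2$reads$BC1, fa)
  expect_equal(c2$vaf, 1.0)
  expect_equal(c2$alt_count, 10L)

  # a single alt read stays below min_alt = 2
  reads3 <- reads
  reads3[[2]]$seq <- substr(genome, 101, 160)
  st3 <- demux_cells(write_test_bam(reads3), barcode_policy = "tag")
  expect_equal(nrow(pileup_call(st3$reads$BC1, fa)), 0)
})

test_that("pileup vaf follows direct count arithmetic (6 ref + 2 alt)", {
  genome <- make_toy_reference()
  fa <- write_test_fasta(genome)
  ref_base <- substr(genome, 250, 250)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  reads <- lapply(1:8, function(i) {
    s <- substr(genome, 231, 270)
    if (i <= 2) substr(s, 20, 20) <- alt_base
    list(qname = paste0("r", i), pos = 231L, seq = s, cb = "X")
  })
  st <- demux_cells(write_test_bam(reads), barcode_policy = "tag")
  calls <- pileup_call(st$reads$X, fa)
  expect_equal(calls$vaf, 0.25)
  expect_equal(calls$depth, 8L)
})

test_that("pileup is reproducible and errors on unknown chromosomes", {
  genome <- make_toy_reference()
  fa <- write_test_fasta(genome)
  sim <- small_bam_sim()
  st <- demux_cells(sim$bam, barcode_policy = "tag")
  r <- st$reads[[1]]
  expect_error(pileup_call(r, fa), "chrS")
  a <- pileup_call(r, sim$fasta)
  b <- pileup_call(r, sim$fasta)
  expect_identical(a, b)
})

test_that("adjacent same-cell calls merge into an MBS record", {
  genome <- make_toy_reference()
  fa <- write_test_fasta(genome)
  r1 <- substr(genome, 401, 440)
  alt1 <- setdiff(c("A", "C", "G", "T"), substr(genome, 420, 420))[1]
  alt2 <- setdiff(c("A", "C", "G", "T"), substr(genome, 421, 421))[1]
  reads <- lapply(1:6, function(i) {
    s <- r1
    substr(s, 20, 20) <- alt1
    substr(s, 21, 21) <- alt2
    list(qname = paste0("r", i), pos = 401L, seq = s, cb = "X")
  })
  st <- demux_cells(write_test_bam(reads), barcode_policy = "tag")
  calls <- pileup_call(st$reads$X, fa)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$substitution_class, "MBS")
  expect_equal(nchar(calls$ref), 2)
  expect_equal(calls$alt, paste0(alt1, alt2))
})

test_that("insertions and deletions in the CIGAR are called as indels", {
  genome <- make_toy_reference()
  fa <- write_test_fasta(genome)
  # 5 reads with a 2-base deletion after 20 aligned bases
  del_reads <- lapply(1:5, function(i)
    list(qname = paste0("d", i), pos = 601L,
         seq = paste0(substr(genome, 601, 620), substr(genome, 623, 642)),
         cigar = "20M2D20M", cb = "X"))
  st <- demux_cells(write_test_bam(del_reads), barcode_policy = "tag")
  calls <- pileup_call(st$reads$X, fa)
  ind <- calls[calls$substitution_class == "indel"]
  expect_equal(nrow(ind), 1)
  expect_equal(ind$pos, 620L)
  expect_equal(nchar(ind$ref), 3)      # anchor + 2 deleted bases
  expect_equal(ind$alt, substr(genome, 620, 620))
})

test_that("region classification follows the precedence and ignores GTF row order", {
  ref <- make_synthetic_reference(out_dir = file.path(tempdir(), "toyref"),
                                  contig_length = 2e4, n_genes = 4,
                                  gene_length = 1000, seed = 3)
  gm1 <- load_gene_model(ref$gtf)
  # shuffle GTF records
  lines <- readLines(ref$gtf)
  set.seed(1); shuf <- file.path(tempdir(), "shuffled.gtf")
  writeLines(sample(lines), shuf)
  gm2 <- load_gene_model(shuf)
  feats <- as.data.frame(ref$features)
  pick_pos <- function(tt) {
    f <- feats[feats$type == tt, ][1, ]
    as.integer((f$start + f$end) %/% 2)
  }
  calls <- data.table::data.table(
    cell_id = "c", chrom = "chrS",
    pos = c(pick_pos("exon"), pick_pos("intron"), pick_pos("five_prime_utr"),
            pick_pos("three_prime_utr"), 5L,
            as.integer(feats[feats$type == "exon", ][1, "end"]) + 1L),
    ref = "A", alt = "G")
  a1 <- annotate_region(calls, gm1)
  a2 <- annotate_region(calls, gm2)
  expect_equal(a1$region_class,
               c("exonic", "intronic", "UTR5", "UTR3", "intergenic",
                 "splicing"))
  expect_equal(a1$region_class, a2$region_class)
  # ncRNA gene exon
  nc_gene <- ref$genes$gene_id[ref$genes$biotype == "lincRNA"]
  nc <- feats[feats$gene_id == nc_gene, ][1, ]
  ncall <- data.table::data.table(cell_id = "c", chrom = "chrS",
                                  pos = as.integer((nc$start + nc$end) %/% 2),
                                  ref = "A", alt = "G")
  expect_equal(annotate_region(ncall, gm1)$region_class, "ncRNA")
})

test_that("call summaries give nondecreasing cumulative unique-site curves", {
  mk_calls <- function(cells, positions) {
    data.table::data.table(cell_id = rep(cells, each = length(positions[[1]])),
                           chrom = "chrT",
                           pos = unlist(positions), ref = "A", alt = "G",
                           depth = 10L, alt_count = 5L, vaf = 0.5,
                           substitution_class = "T>C")
  }
  # disjoint site sets: linear curve
  disj <- mk_calls(c("c1", "c2", "c3"),
                   list(1:5 * 10L, 6:10 * 10L, 11:15 * 10L))
  s <- summarize_calls(disj)
  expect_equal(unname(s$cumulative), c(5, 10, 15))
  # identical sites: flat after the first cell
  same <- mk_calls(c("c1", "c2"), list(1:5 * 10L, 1:5 * 10L))
  s2 <- summarize_calls(same)
  expect_equal(unname(s2$cumulative), c(5, 5))
  # half-shared: slope between the extremes, never decreasing
  half <- mk_calls(c("c1", "c2"), list(1:6 * 10L, 4:9 * 10L))
  s3 <- summarize_calls(half)
  expect_equal(unname(s3$cumulative), c(6, 9))
  expect_true(all(diff(s3$cumulative) >= 0))
  expect_equal(sum(s3$substitution), 12)
  expect_error(summarize_calls(disj[0]), "empty")
})

test_that("per-cell VCF export round-trips key INFO fields", {
  sim <- small_bam_sim()
  calls <- call_variants(sim$bam, sim$fasta, barcode_policy = "tag",
                         gene_model = load_gene_model(sim$gtf))
  out <- file.path(tempdir(), "vcf_out")
  paths <- write_cell_vcfs(calls, out)
  one <- grep("CELL001.vcf", list.files(out, full.names = TRUE), value = TRUE)
  expect_length(one, 1)
  v <- VariantAnnotation::readVcf(one)
  dt <- data.table::as.data.table(calls)[cell_id == "CELL001"]
  expect_equal(length(v), nrow(dt))
  expect_equal(unname(VariantAnnotation::info(v)$DP),
               dt[order(pos)]$depth)
})
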