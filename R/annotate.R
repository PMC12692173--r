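## Genomic region classification of calls from a GTF gene model.
## Precedence when features overlap (one label per call):
## splicing > UTR5 > UTR3 > exonic > ncRNA > intronic > intergenic.

#' Load a GTF gene model for region annotation
#'
#' @param gtf path to a GTF with gene/exon/UTR features (`gene_biotype`
#'   attribute distinguishes ncRNA genes).
#' @param splice_window bases into the intron flanking an exon boundary that
#'   count as splicing.
#' @return list of class `gene_model` with GRanges per region class.
#' @export
load_gene_model <- function(gtf, splice_window = 2L) {
  gr <- rtracklayer::import(gtf)
  ty <- tolower(as.character(gr$type))
  bio <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else
    rep("protein_coding", length(gr))
  nc_types <- c("lincrna", "ncrna", "mirna", "snorna", "snrna", "rrna",
                "lncrna", "antisense")
  is_nc <- tolower(bio) %in% nc_types
  genes <- gr[ty == "gene"]
  exons <- gr[ty == "exon" & !is_nc]
  nc_exons <- gr[ty == "exon" & is_nc]
  utr5 <- gr[ty %in% c("five_prime_utr", "5utr", "utr5")]
  utr3 <- gr[ty %in% c("three_prime_utr", "3utr", "utr3")]
  # splicing: splice_window bases on the intron side of each exon boundary
  exonic_all <- GenomicRanges::reduce(c(GenomicRanges::granges(exons),
                                        GenomicRanges::granges(utr5),
                                        GenomicRanges::granges(utr3)))
  left <- GenomicRanges::flank(exonic_all, splice_window, start = TRUE)
  right <- GenomicRanges::flank(exonic_all, splice_window, start = FALSE)
  splice <- GenomicRanges::intersect(
    GenomicRanges::reduce(c(left, right)),
    GenomicRanges::setdiff(GenomicRanges::reduce(GenomicRanges::granges(genes)),
                           exonic_all))
  structure(list(genes = GenomicRanges::granges(genes),
                 exons = GenomicRanges::granges(exons),
                 nc_exons = GenomicRanges::granges(nc_exons),
                 utr5 = GenomicRanges::granges(utr5),
                 utr3 = GenomicRanges::granges(utr3),
                 splice = splice,
                 gene_ids = if (!is.null(genes$gene_id)) genes$gene_id else
                   as.character(seq_along(genes))),
            class = "gene_model")
}

#' Annotate the genomic region of each call
#'
#' Assigns a single `region_class` per call following the precedence
#' splicing > UTR5 > UTR3 > exonic > ncRNA > intronic > intergenic. Sites on
#' contigs absent from the gene model are intergenic. Also attaches the
#' gene id (for allelic-imbalance lookup) when the site falls in a gene.
#'
#' @param calls a call table (data.table with `chrom`, `pos`).
#' @param gene_model a `gene_model` from [load_gene_model()].
#' @return the call table with `region_class` (and `gene`) filled.
#' @export
annotate_region <- function(calls, gene_model) {
  stopifnot(inherits(gene_model, "gene_model"))
  dt <- as.data.table(calls)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  region <- rep("intergenic", nrow(dt))
  assign_class <- function(region, target, label) {
    if (!length(target)) return(region)
    hits <- GenomicRanges::findOverlaps(gr, target)
    region[unique(S4Vectors::queryHits(hits))] <- label
    region
  }
  # reverse precedence order: later assignments override earlier ones
  region <- assign_class(region, gene_model$genes, "intronic")
  region <- assign_class(region, gene_model$nc_exons, "ncRNA")
  region <- assign_class(region, gene_model$exons, "exonic")
  region <- assign_class(region, gene_model$utr3, "UTR3")
  region <- assign_class(region, gene_model$utr5, "UTR5")
  region <- assign_class(region, gene_model$splice, "splicing")
  dt[, region_class := region]
  gh <- GenomicRanges::findOverlaps(gr, gene_model$genes, select = "first")
  dt[, gene := ifelse(is.na(gh), NA_character_, gene_model$gene_ids[gh])]
  for (a in c("cells", "provenance")) {
    setattr(dt, a, attr(calls, a))
  }
  if (!inherits(dt, "variant_table") && inherits(calls, "variant_table")) {
    setattr(dt, "class", c("variant_table", class(dt)))
  }
  dt[]
}

#' Write one VCF per cell plus a consolidated TSV
#'
#' VCF v4.2 with INFO fields DP, AD, VAF, SBF/SBR (alt strand counts),
#' REGION, SUB (substitution class) and CTX (trinucleotide context).
#'
#' @param table a `variant_table`.
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_cell_vcfs <- function(table, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dt <- as.data.table(table)
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##INFO=<ID=AD,Number=1,Type=Integer,Description="Alt depth">',
           '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">',
           '##INFO=<ID=SBF,Number=1,Type=Integer,Description="Alt forward reads">',
           '##INFO=<ID=SBR,Number=1,Type=Integer,Description="Alt reverse reads">',
           '##INFO=<ID=REGION,Number=1,Type=String,Description="Region class">',
           '##INFO=<ID=SUB,Number=1,Type=String,Description="Substitution class">',
           '##INFO=<ID=CTX,Number=1,Type=String,Description="Trinucleotide context">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  paths <- character(0)
  for (cc in unique(dt$cell_id)) {
    d <- dt[cell_id == cc]
    setorder(d, chrom, pos)
    info <- sprintf("DP=%d;AD=%d;VAF=%.4g;SBF=%s;SBR=%s;REGION=%s;SUB=%s;CTX=%s",
                    d$depth, d$alt_count, d$vaf,
                    ifelse(is.na(d$strand_alt_fwd), ".", d$strand_alt_fwd),
                    ifelse(is.na(d$strand_alt_rev), ".", d$strand_alt_rev),
                    if ("region_class" %in% names(d))
                      ifelse(is.na(d$region_class), ".", d$region_class)
                    else ".",
                    ifelse(is.na(d$substitution_class), ".",
                           d$substitution_class),
                    ifelse(is.na(d$tri_context), ".", d$tri_context))
    body <- paste(d$chrom, d$pos, ".", d$ref, d$alt, ".", "PASS", info,
                  sep = "\t")
    p <- file.path(out_dir, paste0(cc, ".vcf"))
    writeLines(c(hdr, body), p)
    paths <- c(paths, p)
  }
  tsv <- file.path(out_dir, "calls.tsv")
  fwrite(dt, tsv, sep = "\t")
  invisible(c(paths, tsv))
}
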