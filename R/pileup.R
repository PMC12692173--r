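## Per-cell variant detection by pileup over alignment records.
##
## Reads are loaded once with Rsamtools::scanBam, demultiplexed by barcode
## tag (or one file per cell for full-length chemistries), and tallied into
## per-position base counts with quality and strand information. Duplicate,
## secondary and supplementary alignments are ignored; positions are
## reported 1-based (VCF convention) while internal offsets are 0-based
## half-open.

# reference-consuming width of a CIGAR string (M/D/N/=/X)
.cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  for (i in seq_along(cigar)) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    len <- as.integer(sub("[A-Z=]$", "", m))
    op <- sub("^[0-9]+", "", m)
    w[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  w
}

.scan_reads <- function(bam, tag = "CB") {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual"),
    tag = tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (!length(x$pos)) stop("no usable reads in ", bam)
  data.table(qname = x$qname, flag = x$flag, chrom = as.character(x$rname),
             pos = x$pos, mapq = x$mapq, cigar = x$cigar,
             seq = as.character(x$seq), qual = as.character(x$qual),
             strand = as.character(x$strand),
             cb = if (!is.null(x$tag[[tag]])) x$tag[[tag]]
                  else rep(NA_character_, length(x$pos)))
}

#' Demultiplex alignments into per-cell read streams
#'
#' Under the `tag` policy a single barcoded BAM is split on a barcode tag
#' (default `CB`); reads lacking the tag are discarded and counted. Under
#' the `per_file` policy each BAM is one cell, named from the file stem.
#'
#' @param alignment_source one BAM path (`tag`) or a character vector of BAM
#'   paths (`per_file`).
#' @param barcode_policy `"tag"` or `"per_file"`.
#' @param tag barcode tag name.
#' @return list of class `cell_streams`: `reads` (named list of per-cell
#'   read tables) and `discarded` (reads without a barcode).
#' @export
demux_cells <- function(alignment_source, barcode_policy = c("tag", "per_file"),
                        tag = "CB") {
  barcode_policy <- match.arg(barcode_policy)
  if (!length(alignment_source)) stop("empty alignment source")
  if (barcode_policy == "tag") {
    stopifnot(length(alignment_source) == 1)
    dt <- .scan_reads(alignment_source, tag = tag)
    discarded <- sum(is.na(dt$cb))
    if (discarded) .cs_log(discarded, " reads lacked the ", tag, " tag")
    dt <- dt[!is.na(cb)]
    if (!nrow(dt)) stop("no barcoded reads in ", alignment_source)
    reads <- split(dt, by = "cb", keep.by = TRUE)
  } else {
    reads <- lapply(alignment_source, .scan_reads)
    names(reads) <- tools::file_path_sans_ext(basename(alignment_source))
    discarded <- 0L
  }
  structure(list(reads = reads, discarded = discarded,
                 policy = barcode_policy),
            class = "cell_streams")
}

# expand reads into per-base events; returns list(bases = data.table(chrom,
# pos, base, q, fwd), indels = data.table(chrom, pos, type, seq, n))
.expand_reads <- function(reads) {
  simple <- grepl("^[0-9]+M$", reads$cigar)
  out <- list()
  if (any(simple)) {
    r <- reads[simple]
    w <- as.integer(sub("M$", "", r$cigar))
    ridx <- rep(seq_len(nrow(r)), w)
    off <- sequence(w)
    bases <- unlist(strsplit(r$seq, "", fixed = TRUE), use.names = FALSE)
    q <- as.integer(charToRaw(paste(r$qual, collapse = ""))) - 33L
    out$bases <- data.table(chrom = r$chrom[ridx],
                            pos = r$pos[ridx] + off - 1L,
                            base = bases, q = q,
                            fwd = !bitwAnd(r$flag[ridx], 16L))
  }
  indels <- list()
  if (any(!simple)) {
    r <- reads[!simple]
    rows <- vector("list", nrow(r))
    for (i in seq_len(nrow(r))) {
      m <- regmatches(r$cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", r$cigar[i]))[[1]]
      len <- as.integer(sub("[A-Z=]$", "", m))
      op <- sub("^[0-9]+", "", m)
      gpos <- r$pos[i]; spos <- 1L
      sq <- strsplit(r$seq[i], "")[[1]]
      qq <- as.integer(charToRaw(r$qual[i])) - 33L
      ev <- list()
      for (j in seq_along(op)) {
        if (op[j] %in% c("M", "=", "X")) {
          ev[[j]] <- data.table(chrom = r$chrom[i],
                                pos = gpos + seq_len(len[j]) - 1L,
                                base = sq[spos + seq_len(len[j]) - 1L],
                                q = qq[spos + seq_len(len[j]) - 1L],
                                fwd = !bitwAnd(r$flag[i], 16L))
          gpos <- gpos + len[j]; spos <- spos + len[j]
        } else if (op[j] == "I") {
          indels[[length(indels) + 1L]] <- data.table(
            chrom = r$chrom[i], pos = gpos - 1L, type = "ins",
            seq = paste(sq[spos + seq_len(len[j]) - 1L], collapse = ""))
          spos <- spos + len[j]
        } else if (op[j] == "D") {
          indels[[length(indels) + 1L]] <- data.table(
            chrom = r$chrom[i], pos = gpos - 1L, type = "del",
            seq = as.character(len[j]))
          gpos <- gpos + len[j]
        } else if (op[j] == "N") {
          gpos <- gpos + len[j]
        } else if (op[j] == "S") {
          spos <- spos + len[j]
        }
      }
      rows[[i]] <- rbindlist(ev)
    }
    extra <- rbindlist(rows)
    out$bases <- rbindlist(list(out$bases, extra))
  }
  out$indels <- if (length(indels)) rbindlist(indels) else NULL
  out
}

#' Pileup variant calls for one cell
#'
#' Tallies base counts per position from a cell's reads, keeping bases with
#' quality at least `min_base_qual` on reads with mapping quality at least
#' `min_map_qual`, and emits a call for every non-reference allele observed
#' at least `min_alt` times at a position of depth at least `min_depth`.
#' Runs of calls at adjacent positions within the cell are merged into
#' multi-base substitutions (class `MBS`); insertions/deletions seen in the
#' CIGAR are called as class `indel`.
#'
#' @param reads a per-cell read table from [demux_cells()].
#' @param reference FASTA path or [Rsamtools::FaFile].
#' @param min_depth,min_alt,min_base_qual,min_map_qual calling thresholds.
#' @return data.table of calls: chrom, pos (1-based), ref, alt, depth,
#'   alt_count, vaf, mean_base_qual, strand_alt_fwd, strand_alt_rev,
#'   substitution_class (6 pyrimidine classes, `MBS` or `indel`) and
#'   tri_context (`NA` until annotation).
#' @export
pileup_call <- function(reads, reference, min_depth = 2, min_alt = 2,
                        min_base_qual = 20, min_map_qual = 20) {
  stopifnot(min_depth >= 0, min_alt >= 0)
  reads <- reads[reads$mapq >= min_map_qual]
  if (!nrow(reads)) return(.empty_calls())
  fa <- if (is(reference, "FaFile")) reference else Rsamtools::FaFile(reference)
  fa_idx <- Rsamtools::scanFaIndex(fa)
  known <- as.character(GenomicRanges::seqnames(fa_idx))
  missing_chr <- setdiff(unique(reads$chrom), known)
  if (length(missing_chr)) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chr, collapse = ", "))
  }
  ex <- .expand_reads(reads)
  b <- ex$bases[q >= min_base_qual & base %in% c("A", "C", "G", "T")]
  if (!nrow(b)) return(.empty_calls())
  depth_t <- b[, .(depth = .N), by = .(chrom, pos)]
  tally <- b[, .(n = .N, fwd = sum(fwd), qsum = sum(q)),
             by = .(chrom, pos, base)]
  tally <- depth_t[tally, on = c("chrom", "pos")]

  upos <- unique(tally[, .(chrom, pos)])
  gr <- GenomicRanges::GRanges(upos$chrom, IRanges::IRanges(upos$pos, upos$pos))
  upos[, ref := as.character(Biostrings::getSeq(fa, gr))]
  tally <- upos[tally, on = c("chrom", "pos")]

  calls <- tally[base != ref & n >= min_alt & depth >= min_depth,
                 .(chrom, pos, ref, alt = base, depth, alt_count = n,
                   vaf = n / depth, mean_base_qual = qsum / n,
                   strand_alt_fwd = fwd, strand_alt_rev = n - fwd)]
  setorder(calls, chrom, pos, alt)
  calls <- .merge_mbs(calls)

  # indel calls from CIGAR events
  if (!is.null(ex$indels) && nrow(ex$indels)) {
    idt <- ex$indels[, .(alt_count = .N), by = .(chrom, pos, type, seq)]
    idt <- depth_t[idt, on = c("chrom", "pos")]
    idt <- idt[!is.na(depth) & alt_count >= min_alt & depth >= min_depth]
    if (nrow(idt)) {
      anchor_gr <- GenomicRanges::GRanges(
        idt$chrom, IRanges::IRanges(idt$pos, idt$pos +
                                      ifelse(idt$type == "del",
                                             as.integer(idt$seq), 0L)))
      anchor_seq <- as.character(Biostrings::getSeq(fa, anchor_gr))
      ind <- data.table(
        chrom = idt$chrom, pos = idt$pos,
        ref = ifelse(idt$type == "del", anchor_seq,
                     substr(anchor_seq, 1, 1)),
        alt = ifelse(idt$type == "del", substr(anchor_seq, 1, 1),
                     paste0(substr(anchor_seq, 1, 1), idt$seq)),
        depth = idt$depth, alt_count = idt$alt_count,
        vaf = idt$alt_count / idt$depth, mean_base_qual = NA_real_,
        strand_alt_fwd = NA_integer_, strand_alt_rev = NA_integer_,
        substitution_class = "indel", tri_context = NA_character_)
      calls <- rbind(calls, ind)
      setorder(calls, chrom, pos, alt)
    }
  }
  calls[]
}

.empty_calls <- function() {
  data.table(chrom = character(), pos = integer(), ref = character(),
             alt = character(), depth = integer(), alt_count = integer(),
             vaf = numeric(), mean_base_qual = numeric(),
             strand_alt_fwd = integer(), strand_alt_rev = integer(),
             substitution_class = character(), tri_context = character())
}

# merge runs of adjacent single-base calls into MBS records
.merge_mbs <- function(calls) {
  if (!nrow(calls)) {
    calls[, `:=`(substitution_class = character(0),
                 tri_context = character(0))]
    return(calls)
  }
  calls[, substitution_class := NA_character_]
  calls[, tri_context := NA_character_]
  setorder(calls, chrom, pos)
  run <- cumsum(c(1L, (diff(calls$pos) != 1L) |
                    (calls$chrom[-1] != calls$chrom[-nrow(calls)])))
  calls[, run_id := run]
  singles <- calls[, .N, by = run_id][N == 1L, run_id]
  out_s <- calls[run_id %in% singles][, run_id := NULL]
  multi <- calls[!(run_id %in% singles)]
  if (nrow(multi)) {
    out_m <- multi[, .(pos = pos[1], ref = paste(ref, collapse = ""),
                       alt = paste(alt, collapse = ""),
                       depth = min(depth), alt_count = min(alt_count),
                       vaf = min(alt_count) / min(depth),
                       mean_base_qual = mean(mean_base_qual),
                       strand_alt_fwd = min(strand_alt_fwd),
                       strand_alt_rev = min(strand_alt_rev),
                       substitution_class = "MBS",
                       tri_context = NA_character_),
                   by = .(chrom, run_id)][, run_id := NULL]
    setcolorder(out_m, names(out_s))
    out <- rbind(out_s, out_m)
  } else {
    out <- out_s
  }
  setorder(out, chrom, pos, alt)
  out
}

#' Call variants across all cells of an alignment source
#'
#' Demultiplexes, runs [pileup_call()] per cell, classifies substitutions
#' (pyrimidine-strand normalized, with trinucleotide context) and, when a
#' gene model is given, annotates the genomic region of every call.
#'
#' @inheritParams demux_cells
#' @inheritParams pileup_call
#' @param gene_model optional result of [load_gene_model()] or a GTF path.
#' @return data.table of class `variant_table` with one row per
#'   (cell, site, alt); attributes `cells` and `provenance`.
#' @export
call_variants <- function(alignment_source, reference,
                          barcode_policy = c("tag", "per_file"),
                          gene_model = NULL, tag = "CB",
                          min_depth = 2, min_alt = 2, min_base_qual = 20,
                          min_map_qual = 20) {
  barcode_policy <- match.arg(barcode_policy)
  streams <- demux_cells(alignment_source, barcode_policy, tag = tag)
  fa <- if (is(reference, "FaFile")) reference else Rsamtools::FaFile(reference)
  per_cell <- lapply(names(streams$reads), function(cc) {
    calls <- pileup_call(streams$reads[[cc]], fa, min_depth, min_alt,
                         min_base_qual, min_map_qual)
    if (nrow(calls)) calls[, cell_id := cc]
    calls
  })
  tab <- rbindlist(per_cell)
  if (!nrow(tab)) stop("no variant calls produced")
  setcolorder(tab, c("cell_id", setdiff(names(tab), "cell_id")))
  tab <- .classify_substitutions(tab, fa)
  if (!is.null(gene_model)) {
    if (is.character(gene_model)) gene_model <- load_gene_model(gene_model)
    tab <- annotate_region(tab, gene_model)
  }
  setattr(tab, "cells", names(streams$reads))
  setattr(tab, "provenance",
          list(source = alignment_source, policy = barcode_policy,
               min_depth = min_depth, min_alt = min_alt,
               min_base_qual = min_base_qual, min_map_qual = min_map_qual))
  setattr(tab, "class", c("variant_table", class(tab)))
  tab[]
}

# fill substitution_class and tri_context for single-base substitutions
.classify_substitutions <- function(tab, fa) {
  sbs <- which(nchar(tab$ref) == 1 & nchar(tab$alt) == 1 &
                 is.na(tab$substitution_class))
  if (!length(sbs)) return(tab)
  fa_idx <- Rsamtools::scanFaIndex(fa)
  sl <- setNames(BiocGenerics::width(fa_idx),
                 as.character(GenomicRanges::seqnames(fa_idx)))
  pos <- tab$pos[sbs]
  chrom <- tab$chrom[sbs]
  inside <- pos > 1 & pos < sl[chrom]
  tri <- rep(NA_character_, length(sbs))
  if (any(inside)) {
    gr <- GenomicRanges::GRanges(chrom[inside],
                                 IRanges::IRanges(pos[inside] - 1,
                                                  pos[inside] + 1))
    tri[inside] <- as.character(Biostrings::getSeq(fa, gr))
  }
  norm <- normalize_substitution(tab$ref[sbs], tab$alt[sbs],
                                 ifelse(is.na(tri), "NNN", tri))
  tab$substitution_class[sbs] <- norm$sub
  tab$tri_context[sbs] <- ifelse(is.na(tri), NA_character_, norm$context)
  tab
}

#' Per-cell allele counts at a fixed set of sites
#'
#' Re-tallies every cell's reads at the given sites and reports reference
#' and alternate read counts wherever the cell has any coverage — including
#' cells with no alternate reads, whose genotype-0 evidence a call table
#' alone cannot provide.
#'
#' @inheritParams demux_cells
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (e.g. the
#'   unique sites of a filtered call table).
#' @param min_base_qual,min_map_qual quality cutoffs matching the caller's.
#' @return data.table: cell_id, chrom, pos, ref, alt, ref_count, alt_count,
#'   one row per (cell, site) with coverage >= 1.
#' @export
site_counts <- function(alignment_source, sites,
                        barcode_policy = c("tag", "per_file"), tag = "CB",
                        min_base_qual = 20, min_map_qual = 20) {
  barcode_policy <- match.arg(barcode_policy)
  streams <- demux_cells(alignment_source, barcode_policy, tag = tag)
  sites <- unique(as.data.table(sites)[, .(chrom, pos, ref, alt)])
  out <- vector("list", length(streams$reads))
  for (i in seq_along(streams$reads)) {
    reads <- streams$reads[[i]]
    reads <- reads[reads$mapq >= min_map_qual]
    if (!nrow(reads)) next
    ex <- .expand_reads(reads)
    b <- ex$bases[q >= min_base_qual & base %in% c("A", "C", "G", "T")]
    b <- b[sites[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
    if (!nrow(b)) next
    tal <- b[, .(depth = .N), by = .(chrom, pos)]
    altc <- b[sites, on = c("chrom", "pos"), nomatch = NULL][
      base == alt, .(alt_count = .N), by = .(chrom, pos)]
    tal <- merge(tal, altc, by = c("chrom", "pos"), all.x = TRUE)
    tal[is.na(alt_count), alt_count := 0L]
    tal <- merge(tal, sites, by = c("chrom", "pos"))
    tal[, `:=`(cell_id = names(streams$reads)[i],
               ref_count = depth - alt_count)]
    out[[i]] <- tal[, .(cell_id, chrom, pos, ref, alt, ref_count, alt_count)]
  }
  rbindlist(out)
}

#' Summaries of a variant call table
#'
#' @param table a `variant_table`.
#' @return list: `per_cell` (calls per cell), `cumulative` (unique sites as
#'   cells accumulate, nondecreasing), `region` and `substitution`
#'   histograms.
#' @export
summarize_calls <- function(table) {
  dt <- as.data.table(table)
  if (!nrow(dt)) stop("empty call table")
  cells <- attr(table, "cells")
  if (is.null(cells)) cells <- sort(unique(dt$cell_id))
  per_cell <- dt[, .N, by = cell_id][match(cells, cell_id), ]
  per_cell[is.na(N), N := 0L]
  per_cell[, cell_id := cells]
  seen <- character(0)
  cum <- integer(length(cells))
  dt[, site_key := .site_key(chrom, pos, ref, alt)]
  for (i in seq_along(cells)) {
    seen <- union(seen, dt[cell_id == cells[i], site_key])
    cum[i] <- length(seen)
  }
  list(per_cell = per_cell,
       cumulative = setNames(cum, cells),
       region = if ("region_class" %in% names(dt))
         table(dt$region_class) else NULL,
       substitution = table(dt$substitution_class))
}
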