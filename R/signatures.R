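## 96-context mutational signatures (6 pyrimidine-centric substitution
## classes x 16 flanking-base pairs), in the conventional COSMIC ordering.

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide context labels (COSMIC ordering)
#'
#' `A[C>A]A, A[C>A]C, ..., T[T>G]T`: substitutions in the order C>A, C>G,
#' C>T, T>A, T>C, T>G; within each, the 16 flank pairs alphabetically.
#'
#' @return character vector of length 96.
#' @export
context_96_levels <- function() {
  out <- character(0)
  for (s in .SUBS) for (b5 in .BASES) for (b3 in .BASES) {
    out <- c(out, paste0(b5, "[", s, "]", b3))
  }
  out
}

#' Normalize a substitution and its trinucleotide context to the pyrimidine strand
#'
#' Purine reference bases (A/G) are reverse-complemented: the context is
#' reverse-complemented and ref/alt are complemented, so the middle base is
#' always C or T.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context 3-mer centered on the site, reference strand.
#' @return data.frame with `sub` ("C>T" etc.), `context` (normalized 3-mer)
#'   and `label` ("A[C>T]G" etc.).
#' @export
normalize_substitution <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  pur <- ref %in% c("A", "G")
  ref[pur] <- unname(.complement[ref[pur]])
  alt[pur] <- unname(.complement[alt[pur]])
  if (any(pur)) context[pur] <- .revcomp(context[pur])
  sub <- paste0(ref, ">", alt)
  label <- paste0(substr(context, 1, 1), "[", sub, "]", substr(context, 3, 3))
  data.frame(sub = sub, context = context, label = label,
             stringsAsFactors = FALSE)
}

#' 96-context mutation spectrum
#'
#' Counts single-base substitutions into the 96 trinucleotide context
#' classes, reverse-complementing purine-reference calls onto the pyrimidine
#' strand. Flanking bases come from the call table's `tri_context` column
#' when present, else from `reference` (an [Rsamtools::FaFile] path or
#' object). By default a recurrent site is counted once per cell carrying it
#' (`per = "cell_site"`); `per = "site"` counts each unique site once.
#'
#' @param calls a variant call table (see [pileup_call()]); only rows with
#'   single-base `ref`/`alt` contribute.
#' @param reference optional FASTA path/FaFile for flanking bases.
#' @param per counting unit: `"cell_site"` or `"site"`.
#' @return list of class `signature_profile`: `counts` (named, length 96)
#'   and `fractions` (sums to 1; all-`NA` when no mutations counted).
#' @export
signature_96 <- function(calls, reference = NULL,
                         per = c("cell_site", "site")) {
  per <- match.arg(per)
  dt <- as.data.table(calls)
  lev <- context_96_levels()
  sbs <- dt[nchar(ref) == 1 & nchar(alt) == 1 &
              ref %in% .BASES & alt %in% .BASES & ref != alt]
  if (per == "site" && nrow(sbs)) {
    sbs <- unique(sbs, by = c("chrom", "pos", "ref", "alt"))
  } else if (nrow(sbs)) {
    sbs <- unique(sbs, by = c("cell_id", "chrom", "pos", "ref", "alt"))
  }
  if (nrow(sbs) == 0) {
    counts <- setNames(numeric(96), lev)
    return(structure(list(counts = counts,
                          fractions = setNames(rep(NA_real_, 96), lev),
                          n = 0L, flagged = "no single-base substitutions"),
                     class = "signature_profile"))
  }
  if ("tri_context" %in% names(sbs) && !anyNA(sbs$tri_context)) {
    labels <- ifelse(substr(sbs$tri_context, 2, 2) %in% c("C", "T"),
                     paste0(substr(sbs$tri_context, 1, 1), "[",
                            substr(sbs$tri_context, 2, 2), ">",
                            # alt on the already-normalized strand:
                            ifelse(sbs$ref %in% c("C", "T"), sbs$alt,
                                   unname(.complement[sbs$alt])),
                            "]", substr(sbs$tri_context, 3, 3)),
                     NA_character_)
    miss <- is.na(labels)
  } else {
    labels <- rep(NA_character_, nrow(sbs))
    miss <- rep(TRUE, nrow(sbs))
  }
  if (any(miss)) {
    if (is.null(reference)) {
      stop("calls lack tri_context; supply `reference` for flanking bases")
    }
    fa <- if (is(reference, "FaFile")) reference else Rsamtools::FaFile(reference)
    seqlen <- Rsamtools::scanFaIndex(fa)
    sl <- setNames(BiocGenerics::width(seqlen),
                   as.character(GenomicRanges::seqnames(seqlen)))
    m <- sbs[miss]
    inside <- m$pos > 1 & m$pos < sl[m$chrom]
    if (any(!inside)) .cs_log(sum(!inside), " calls skipped: flank off contig end")
    tri <- rep(NA_character_, nrow(m))
    if (any(inside)) {
      gr <- GenomicRanges::GRanges(m$chrom[inside],
                                   IRanges::IRanges(m$pos[inside] - 1,
                                                    m$pos[inside] + 1))
      tri[inside] <- as.character(Biostrings::getSeq(fa, gr))
    }
    norm <- normalize_substitution(m$ref, m$alt, ifelse(is.na(tri), "NNN", tri))
    labels[miss] <- ifelse(is.na(tri), NA_character_, norm$label)
  }
  labels <- labels[!is.na(labels) & labels %in% lev]
  counts <- table(factor(labels, levels = lev))
  counts <- setNames(as.numeric(counts), lev)
  fr <- if (sum(counts) > 0) counts / sum(counts) else setNames(rep(NA_real_, 96), lev)
  structure(list(counts = counts, fractions = fr, n = sum(counts)),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("signature_profile:", x$n, "substitutions;")
  if (x$n > 0) {
    top <- sort(x$fractions, decreasing = TRUE)[1:3]
    cat(" top contexts:", paste(names(top), signif(top, 2), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Per-cell 96-context spectra
#'
#' @inheritParams signature_96
#' @return matrix (cells x 96) of raw counts.
#' @export
cell_signatures <- function(calls, reference = NULL) {
  dt <- as.data.table(calls)
  cells <- sort(unique(dt$cell_id))
  out <- matrix(0, length(cells), 96,
                dimnames = list(cells, context_96_levels()))
  for (cc in cells) {
    p <- signature_96(dt[cell_id == cc], reference = reference)
    out[cc, ] <- p$counts
  }
  out
}

#' Cosine similarity between two signature profiles
#'
#' @param a,b `signature_profile` objects or numeric vectors of length 96.
#' @return cosine in `[0, 1]`.
#' @export
signature_cosine <- function(a, b) {
  va <- if (inherits(a, "signature_profile")) a$counts else a
  vb <- if (inherits(b, "signature_profile")) b$counts else b
  cosine_similarity(va, vb)
}

#' Bar plot of a 96-context spectrum
#'
#' @param profile a `signature_profile`.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_signature <- function(profile, title = "Mutational signature") {
  lev <- context_96_levels()
  df <- data.frame(context = factor(lev, levels = lev),
                   fraction = as.numeric(profile$fractions),
                   sub = sub(".*\\[(.*)\\].*", "\\1", lev))
  ggplot2::ggplot(df, ggplot2::aes(x = context, y = fraction, fill = sub)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~sub, scales = "free_x") +
    ggplot2::labs(title = title, x = NULL, y = "fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 4),
                   legend.position = "none")
}
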