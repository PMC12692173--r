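## Spot-level spatial integration. Spots are pseudo-cells with coordinates;
## the genotype pipeline treats them identically. Clone labels are
## intersected with expression clusters to name subclones.

#' Filter spots by mutation evidence
#'
#' Spots (rows of the genotype matrix) with fewer than `min_mutations`
#' observed sites are removed; spot-level data carry several cells per ROI
#' spot, so the default is stricter than for single cells.
#'
#' @param gm a `genotype_matrix` built with spots as cells.
#' @param min_mutations minimum observed genotypes per spot.
#' @return list: `matrix` (retained spots), `retained`, `removed`,
#'   `utilization` (retained fraction).
#' @export
filter_spots <- function(gm, min_mutations = 20) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_obs <- rowSums(!is.na(gm$genotype))
  keep <- n_obs >= min_mutations
  out <- gm
  out$genotype <- gm$genotype[keep, , drop = FALSE]
  out$ref_count <- gm$ref_count[keep, , drop = FALSE]
  out$alt_count <- gm$alt_count[keep, , drop = FALSE]
  out$cells <- gm$cells[keep]
  list(matrix = out, retained = gm$cells[keep], removed = gm$cells[!keep],
       utilization = mean(keep))
}

#' Intersect clone labels with expression clusters into subclones
#'
#' Every non-empty (expression cluster x clone) combination becomes a
#' subclone. Within an expression cluster, combinations smaller than
#' `min_group` are merged into the cluster's dominant clone. Clusters whose
#' spots all share one clone keep their plain cluster name; split clusters
#' get `<type>_<k>` subclone names.
#'
#' @param clone_labels named vector (spot -> clone).
#' @param expression_clusters named vector (spot -> expression cluster);
#'   `NULL` returns clone labels unchanged with a warning.
#' @param min_group minimum spots per subclone before merging.
#' @return named character vector of subclone labels per spot.
#' @export
intersect_clones_with_expression <- function(clone_labels,
                                             expression_clusters,
                                             min_group = 10) {
  if (is.null(expression_clusters)) {
    warning("no expression clusters supplied; returning clone labels")
    return(clone_labels)
  }
  spots <- names(clone_labels)
  if (is.null(spots)) stop("clone_labels must be named by spot id")
  ec <- expression_clusters[spots]
  if (anyNA(ec)) stop("expression clusters missing for some spots")
  out <- setNames(character(length(spots)), spots)
  for (ty in unique(ec)) {
    sel <- which(ec == ty)
    cl <- clone_labels[sel]
    tab <- sort(table(cl), decreasing = TRUE)
    dominant <- names(tab)[1]
    small <- names(tab)[tab < min_group & names(tab) != dominant]
    cl[cl %in% small] <- dominant
    groups <- sort(unique(cl))
    if (length(groups) == 1) {
      out[sel] <- ty
    } else {
      sub_id <- match(cl, groups)
      out[sel] <- paste0(ty, "_", sub_id)
    }
  }
  out
}

#' Plot clonal structure on the tissue section
#'
#' One marker per retained spot colored by clone/subclone; filtered spots
#' are drawn hollow. Coordinates are image pixels when present in
#' `spot_table` (`pxl_col`, `pxl_row`), else array row/col.
#'
#' @param spot_table data.frame with `spot_id`, coordinates (`pxl_col` /
#'   `pxl_row` or `array_col` / `array_row`) and optional `in_tissue`.
#' @param clone_labels named vector spot -> clone; spots absent from it are
#'   treated as filtered.
#' @return a ggplot object.
#' @export
render_spatial_clones <- function(spot_table, clone_labels) {
  st <- as.data.table(spot_table)
  if (all(c("pxl_col", "pxl_row") %in% names(st))) {
    st[, `:=`(x = pxl_col, y = pxl_row)]
  } else if (all(c("array_col", "array_row") %in% names(st))) {
    st[, `:=`(x = array_col, y = array_row)]
  } else stop("spot_table lacks coordinates")
  st[, clone := as.character(clone_labels[as.character(spot_id)])]
  st[, retained := !is.na(clone)]
  ggplot2::ggplot() +
    ggplot2::geom_point(data = st[retained == FALSE],
                        ggplot2::aes(x = x, y = y),
                        shape = 1, color = "grey60", size = 2) +
    ggplot2::geom_point(data = st[retained == TRUE],
                        ggplot2::aes(x = x, y = y, color = clone),
                        size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, color = "clone") +
    ggplot2::theme_minimal()
}

#' Read a Visium-style tissue positions table
#' @param tsv TSV/CSV with columns barcode, in_tissue, array_row, array_col,
#'   pxl_row, pxl_col (header optional, Visium layout).
#' @return data.table with `spot_id` and coordinate columns.
#' @export
read_spot_positions <- function(tsv) {
  st <- fread(tsv)
  if (!("spot_id" %in% names(st))) {
    cn <- c("spot_id", "in_tissue", "array_row", "array_col", "pxl_row",
            "pxl_col")
    setnames(st, seq_len(min(ncol(st), length(cn))),
             cn[seq_len(min(ncol(st), length(cn)))])
  }
  st
}
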