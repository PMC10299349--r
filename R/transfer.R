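# Applying fitted panels to new data. Panel genes absent from the target are
# dropped from numerators and denominators alike, and the number of panel
# genes actually found is always reported so silent shrinkage stays visible.
# Matching is exact on gene id; cross-species use requires pre-mapped
# orthologs.

panel_genes_of <- function(panel) {
  if (inherits(panel, "MarkerPanel")) panel$genes else unique(as.character(panel))
}

match_panel <- function(panel, target_gene_ids, error_on_empty = TRUE) {
  genes <- unique(panel_genes_of(panel))
  present <- intersect(genes, target_gene_ids)
  if (!length(present) && error_on_empty)
    stop("no panel gene present in target; missing: ",
         paste(utils::head(setdiff(genes, target_gene_ids), 10),
               collapse = ", "))
  list(present = present, missing = setdiff(genes, target_gene_ids))
}

panel_depths <- function(panel, b) {
  stopifnot(inherits(b, "BinaryMatrix"))
  pm <- match_panel(panel, rownames(b$x))
  depth <- as.integer(Matrix::colSums(b$x[pm$present, , drop = FALSE]))
  names(depth) <- colnames(b$x)
  list(depth = depth, n_found = length(pm$present), missing = pm$missing)
}

#' Depth classifier
#'
#' The binary rule declaring a cell "class positive" when it expresses at
#' least `d` panel genes (restricted to panel genes present in the target).
#' `d = 0` is vacuously positive.
#'
#' @param panel a `MarkerPanel` or character vector of gene ids.
#' @param b target `BinaryMatrix`.
#' @param d covering depth.
#' @param strict if `TRUE`, require strictly more than `d` expressed genes.
#' @return named 0/1 integer vector, one per target cell.
#' @export
depth_classifier <- function(panel, b, d, strict = FALSE) {
  pd <- panel_depths(panel, b)
  as.integer(if (strict) pd$depth > d else pd$depth >= d) |>
    stats::setNames(names(pd$depth))
}

#' Per-cell expressed proportion of a panel
#'
#' For each target cell, the fraction of panel genes (among those present in
#' the target) expressed at non-zero level. Duplicate panel entries are
#' deduplicated; gene order is irrelevant.
#'
#' @inheritParams depth_classifier
#' @return list with `proportion` (named numeric per cell) and
#'   `panel_genes_found`.
#' @export
cell_proportions <- function(panel, b) {
  pd <- panel_depths(panel, b)
  list(proportion = pd$depth / pd$n_found,
       panel_genes_found = pd$n_found,
       missing_genes = pd$missing)
}

#' Per-class covering rates of a panel on a target dataset
#'
#' For each target class, the fraction of its cells expressing at least `d`
#' (or, with `strict = TRUE`, more than `d`) panel genes.
#'
#' @inheritParams depth_classifier
#' @param labels class labels of the target cells (or `NULL` to use
#'   `b$labels`).
#' @return named numeric vector of rates per target class, with attributes
#'   `panel_genes_found` and `depth`.
#' @export
class_covering_rates <- function(panel, b, labels = NULL, d, strict = FALSE) {
  labels <- resolve_labels(b, labels)
  hit <- depth_classifier(panel, b, d, strict = strict)
  rates <- tapply(hit, labels, mean)
  out <- as.numeric(rates)
  names(out) <- names(rates)
  attr(out, "panel_genes_found") <- panel_depths(panel, b)$n_found
  attr(out, "depth") <- d
  out
}

#' Bulk transfer score
#'
#' For bulk samples, sums the expression of the panel genes present in the
#' target within each sample and divides by the maximum sum observed, so the
#' top sample scores exactly 1.
#'
#' @param panel a `MarkerPanel` or character vector of gene ids.
#' @param m target `ExpressionMatrix` of genes x samples (raw or normalized;
#'   whatever is supplied is used and recorded by the caller).
#' @return named numeric vector of scores in `[0, 1]`, with attribute
#'   `panel_genes_found`.
#' @export
bulk_transfer <- function(panel, m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  pm <- match_panel(panel, rownames(m$counts))
  sums <- Matrix::colSums(m$counts[pm$present, , drop = FALSE])
  top <- max(sums)
  if (top <= 0) stop("all samples have zero summed panel expression")
  out <- as.numeric(sums / top)
  names(out) <- colnames(m$counts)
  attr(out, "panel_genes_found") <- length(pm$present)
  out
}
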