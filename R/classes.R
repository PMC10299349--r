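#' Construct an ExpressionMatrix
#'
#' Lightweight container for a genes x cells non-negative count matrix with
#' unique gene and cell identifiers and an optional categorical class label
#' per cell. Counts may be any non-negative numbers (some pipelines emit
#' normalized values); binarization later applies a strict `> theta` rule.
#'
#' @param counts numeric matrix or [Matrix::Matrix] (genes in rows, cells in
#'   columns) with non-negative entries. Dimnames, if present, are used as
#'   gene/cell ids unless `gene_ids`/`cell_ids` are given.
#' @param gene_ids character vector of unique gene identifiers.
#' @param cell_ids character vector of unique cell identifiers.
#' @param labels optional vector (or factor) of class labels, one per cell,
#'   or a named vector keyed by cell id.
#' @return an object of class `ExpressionMatrix` with elements `counts`
#'   (a sparse [Matrix::dgCMatrix]), and `labels` (factor or `NULL`).
#' @export
expression_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL,
                              labels = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or provide dimnames)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") does not match nrow(counts) (",
         nrow(counts), ")")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length (", length(cell_ids), ") does not match ncol(counts) (",
         ncol(counts), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
    paste(utils::head(gene_ids[duplicated(gene_ids)], 3), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
    paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (min(counts@x, 0) < 0) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      missing <- setdiff(cell_ids, names(labels))
      if (length(missing))
        stop("labels missing for cells: ",
             paste(utils::head(missing, 3), collapse = ", "))
      labels <- labels[cell_ids]
    }
    if (length(labels) != length(cell_ids))
      stop("labels length (", length(labels),
           ") does not match number of cells (", length(cell_ids), ")")
    if (anyNA(labels)) stop("labels contain NA")
    labels <- factor(as.character(labels))
    names(labels) <- cell_ids
  }
  structure(list(counts = counts, labels = labels), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  if (!is.null(x$labels))
    cat("  classes:", paste(levels(x$labels), collapse = ", "), "\n")
  invisible(x)
}

gene_ids <- function(m) rownames(m$counts %||% m$x)
cell_ids <- function(m) colnames(m$counts %||% m$x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a cover configuration
#'
#' Bundles the tunable parameters of panel selection: the covering depth `d`
#' (how many panel genes a cell must express to count as covered), the
#' tolerated uncovered fraction `alpha` (target covering rate is `1 - alpha`),
#' the binarization threshold `theta`, the gene weight scheme, candidate
#' filters, and solver options.
#'
#' @param depth positive integer; minimum number of expressed panel genes for
#'   a cell to be covered.
#' @param alpha numeric in `[0, 1)`; tolerated uncovered fraction of a class.
#' @param theta non-negative binarization threshold (counts strictly greater
#'   than `theta` are "expressed"; default 0, i.e. raw count >= 1).
#' @param scheme weight scheme, one of `"mean_ratio"` (default), `"max_ratio"`,
#'   `"lognorm_ratio"`, `"bonferroni"`, `"log_complement"`.
#' @param min_expr minimum in-class expression probability for a candidate
#'   gene (default 0.1).
#' @param max_weight candidate weight cutoff (default 1; genes with
#'   `w > max_weight` are excluded).
#' @param solver `"ilp"` (exact branch and bound), `"greedy"` or
#'   `"brute_force"`.
#' @param time_limit solver wall-clock limit in seconds (default 600).
#' @param mip_gap relative optimality gap tolerated before the solver stops
#'   (default 0: proven optimum).
#' @param node_limit branch-and-bound node budget before the incumbent is
#'   returned with status `gap_reported`.
#' @param seed integer seed recorded in provenance and used for any stochastic
#'   component.
#' @param norm_target per-cell target sum for log-normalization used by the
#'   `lognorm_ratio` scheme (default 1e4).
#' @return a `CoverConfig` list.
#' @export
cover_config <- function(depth = 1L, alpha = 0, theta = 0,
                         scheme = c("mean_ratio", "max_ratio", "lognorm_ratio",
                                    "bonferroni", "log_complement"),
                         min_expr = 0.1, max_weight = 1,
                         solver = c("ilp", "greedy", "brute_force"),
                         time_limit = 600, mip_gap = 0, node_limit = 5e7,
                         seed = 1L, norm_target = 1e4) {
  scheme <- match.arg(scheme)
  solver <- match.arg(solver)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth must be a positive integer")
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  if (theta < 0) stop("theta must be non-negative")
  if (min_expr < 0 || min_expr > 1) stop("min_expr must lie in [0, 1]")
  structure(list(depth = depth, alpha = alpha, theta = theta, scheme = scheme,
                 min_expr = min_expr, max_weight = max_weight, solver = solver,
                 time_limit = time_limit, mip_gap = mip_gap,
                 node_limit = node_limit, seed = as.integer(seed),
                 norm_target = norm_target),
            class = "CoverConfig")
}

#' Construct a MarkerPanel
#'
#' @param class_name class the panel marks.
#' @param genes ordered character vector of selected gene ids (unique).
#' @param weights numeric weights of the selected genes (same length/order).
#' @param config the `CoverConfig` used.
#' @param achieved_rate fraction of class cells covered at the fitted depth,
#'   recomputed from the panel (not trusted from the solver).
#' @param solver_status one of `"optimal"`, `"gap_reported"`, `"greedy"`,
#'   `"infeasible"`.
#' @param diagnostics optional list (gap, max feasible rate, ...).
#' @return a `MarkerPanel`.
#' @export
marker_panel <- function(class_name, genes, weights, config,
                         achieved_rate = NA_real_,
                         solver_status = c("optimal", "gap_reported",
                                           "greedy", "infeasible"),
                         diagnostics = list()) {
  solver_status <- match.arg(solver_status)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("panel genes must be unique")
  if (length(genes) != length(weights))
    stop("genes and weights must have equal length")
  structure(list(class_name = as.character(class_name), genes = genes,
                 weights = as.numeric(weights), config = config,
                 achieved_rate = achieved_rate,
                 objective = sum(as.numeric(weights)),
                 solver_status = solver_status, diagnostics = diagnostics),
            class = "MarkerPanel")
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat(sprintf("MarkerPanel[%s]: %d genes, objective %.4g, rate %.3f (%s)\n",
              x$class_name, length(x$genes), x$objective,
              x$achieved_rate, x$solver_status))
  invisible(x)
}

#' Construct a PanelSet
#'
#' @param panels list of `MarkerPanel`s (one per class); names default to the
#'   panels' class names.
#' @return a `PanelSet` with a `global_panel` equal to the union of all
#'   per-class gene lists.
#' @export
panel_set <- function(panels) {
  if (!length(panels)) {
    return(structure(list(panels = list(), global_panel = character(0)),
                     class = "PanelSet"))
  }
  stopifnot(all(vapply(panels, inherits, logical(1), "MarkerPanel")))
  names(panels) <- vapply(panels, `[[`, character(1), "class_name")
  if (anyDuplicated(names(panels))) stop("duplicate class names in panel set")
  global <- unique(unlist(lapply(panels, `[[`, "genes"), use.names = FALSE))
  structure(list(panels = panels, global_panel = as.character(global)),
            class = "PanelSet")
}

#' @export
print.PanelSet <- function(x, ...) {
  cat("PanelSet:", length(x$panels), "classes,",
      length(x$global_panel), "genes in global panel\n")
  for (p in x$panels) print(p)
  invisible(x)
}
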