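#' Read an expression matrix from disk
#'
#' Two layouts are supported: Matrix Market coordinate format plus two TSV
#' metadata files (`genes.tsv`, `cells.tsv`, both with a mandatory header
#' row), or a dense CSV with gene ids in the first column and cell ids in the
#' header. Orientation is never guessed: if the file stores cells in rows,
#' say so with `orientation = "cells_by_genes"`.
#'
#' @param counts path to the `.mtx` file or the dense CSV.
#' @param genes,cells paths to the TSV metadata files (mtx format only). The
#'   first column holds the ids; `cells` may carry a label column.
#' @param format `"mtx"` or `"csv"`.
#' @param label_col name of the column in `cells` (or `NULL`) holding class
#'   labels.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(counts, genes = NULL, cells = NULL,
                        format = c("mtx", "csv"), label_col = NULL,
                        orientation = c("genes_by_cells", "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(counts)) stop("counts file not found: ", counts)
  if (format == "mtx") {
    if (is.null(genes) || is.null(cells))
      stop("mtx format requires 'genes' and 'cells' metadata files")
    for (f in c(genes, cells))
      if (!file.exists(f)) stop("metadata file not found: ", f)
    m <- Matrix::readMM(counts)
    gtab <- utils::read.delim(genes, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
    ctab <- utils::read.delim(cells, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    if (nrow(gtab) != nrow(m))
      stop("dimension mismatch: ", genes, " has ", nrow(gtab),
           " rows but matrix has ", nrow(m), " gene rows")
    if (nrow(ctab) != ncol(m))
      stop("dimension mismatch: ", cells, " has ", nrow(ctab),
           " rows but matrix has ", ncol(m), " cell columns")
    labels <- NULL
    if (!is.null(label_col)) {
      if (!label_col %in% names(ctab))
        stop("label column '", label_col, "' not found in ", cells)
      labels <- ctab[[label_col]]
    }
    expression_matrix(m, gene_ids = gtab[[1]], cell_ids = ctab[[1]],
                      labels = labels)
  } else {
    tab <- utils::read.csv(counts, header = TRUE, row.names = 1,
                           check.names = FALSE)
    m <- as.matrix(tab)
    if (orientation == "cells_by_genes") m <- t(m)
    expression_matrix(m, gene_ids = rownames(m), cell_ids = colnames(m))
  }
}

#' Write an expression matrix as mtx + TSV metadata
#'
#' @param m an `ExpressionMatrix`.
#' @param prefix output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.genes.tsv` and `<prefix>.cells.tsv` (with a `label` column when
#'   labels are present).
#' @return invisibly, the three file paths.
#' @export
write_matrix <- function(m, prefix) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  paths <- paste0(prefix, c(".mtx", ".genes.tsv", ".cells.tsv"))
  Matrix::writeMM(m$counts, paths[1])
  utils::write.table(data.frame(gene_id = rownames(m$counts)),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  ctab <- data.frame(cell_id = colnames(m$counts))
  if (!is.null(m$labels)) ctab$label <- as.character(m$labels)
  utils::write.table(ctab, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Binarize an expression matrix
#'
#' A gene is deemed expressed in a cell when its count is strictly greater
#' than `theta`; with raw integer counts and the default `theta = 0` this is
#' exactly "raw count >= 1". Binarization at `theta = 0` is invariant to any
#' positive rescaling of the counts and idempotent on already-binary data.
#'
#' @param m an `ExpressionMatrix` (or a `BinaryMatrix`, returned as is when
#'   `theta = 0`).
#' @param theta non-negative threshold in count units.
#' @return a `BinaryMatrix`: list with `x` (sparse 0/1 genes x cells matrix),
#'   `theta`, and `labels` carried over from the source.
#' @export
binarize <- function(m, theta = 0) {
  if (theta < 0) stop("theta must be non-negative")
  if (inherits(m, "BinaryMatrix")) {
    if (theta == 0) return(m)
    m <- structure(list(counts = m$x, labels = m$labels),
                   class = "ExpressionMatrix")
  }
  stopifnot(inherits(m, "ExpressionMatrix"))
  x <- m$counts
  x@x <- as.numeric(x@x > theta)
  x <- Matrix::drop0(x)
  structure(list(x = x, theta = theta, labels = m$labels),
            class = "BinaryMatrix")
}

#' @export
dim.BinaryMatrix <- function(x) dim(x$x)

#' @export
print.BinaryMatrix <- function(x, ...) {
  cat("BinaryMatrix:", nrow(x$x), "genes x", ncol(x$x),
      sprintf("cells (theta = %g, %.1f%% nonzero)\n", x$theta,
              100 * length(x$x@x) / prod(dim(x$x))))
  invisible(x)
}

PANEL_SCHEMA_VERSION <- "1.0"

#' Serialize a panel set
#'
#' Writes a versioned JSON document preserving gene order, weights, config,
#' achieved rates and solver status to full precision, and a flat TSV
#' (`class`, `gene`, `weight`, `rank`) next to it.
#'
#' @param ps a `PanelSet`.
#' @param path output JSON path; the TSV is written to the same path with a
#'   `.tsv` extension.
#' @return invisibly, the JSON path.
#' @export
write_panels <- function(ps, path) {
  stopifnot(inherits(ps, "PanelSet"))
  doc <- list(
    schema_version = PANEL_SCHEMA_VERSION,
    global_panel = ps$global_panel,
    panels = lapply(unname(ps$panels), function(p) {
      list(class_name = p$class_name, genes = p$genes, weights = p$weights,
           achieved_rate = p$achieved_rate, objective = p$objective,
           solver_status = p$solver_status,
           config = unclass(p$config))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  tsv <- panels_to_table(ps)
  utils::write.table(tsv, sub("\\.json$", "", path) |> paste0(".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a panel set to a table
#'
#' @param ps a `PanelSet`.
#' @return data.frame with columns class, gene, weight, rank.
#' @export
panels_to_table <- function(ps) {
  rows <- lapply(ps$panels, function(p) {
    if (!length(p$genes))
      return(data.frame(class = character(0), gene = character(0),
                        weight = numeric(0), rank = integer(0)))
    data.frame(class = p$class_name, gene = p$genes, weight = p$weights,
               rank = seq_along(p$genes))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(class = character(0), gene = character(0),
                      weight = numeric(0), rank = integer(0))
  out
}

#' Read a panel set written by [write_panels()]
#'
#' @param path JSON path.
#' @return a `PanelSet`.
#' @export
read_panels <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), PANEL_SCHEMA_VERSION))
    stop("unknown panel schema version: ",
         doc$schema_version %||% "<missing>")
  panels <- lapply(doc$panels, function(p) {
    cfg <- p$config
    config <- if (is.null(cfg)) NULL else
      cover_config(depth = cfg$depth, alpha = cfg$alpha, theta = cfg$theta,
                   scheme = cfg$scheme, min_expr = cfg$min_expr,
                   max_weight = cfg$max_weight, solver = cfg$solver,
                   time_limit = cfg$time_limit, mip_gap = cfg$mip_gap,
                   node_limit = cfg$node_limit, seed = cfg$seed,
                   norm_target = cfg$norm_target)
    marker_panel(p$class_name,
                 genes = unlist(p$genes) %||% character(0),
                 weights = unlist(p$weights) %||% numeric(0),
                 config = config,
                 achieved_rate = p$achieved_rate %||% NA_real_,
                 solver_status = p$solver_status)
  })
  panel_set(panels)
}
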