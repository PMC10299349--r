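#' Map cell types across datasets via normalized covering rates
#'
#' For each source class k, the raw rate against target class k' is the
#' fraction of k' cells expressing at least `depth` genes of panel M_k
#' (restricted to genes present in the target). Raw rates are then 0-1
#' normalized across target classes, and a pair (k, k') maps when the
#' normalized rate strictly exceeds `threshold`. When a panel has fewer
#' present genes than `depth`, the depth is lowered to the panel size for
#' that class and recorded. Source classes whose raw rates are all equal
#' cannot be normalized and are reported unmapped with a warning.
#'
#' @param ps a `PanelSet` of source panels.
#' @param b target `BinaryMatrix`.
#' @param labels target class labels (or `NULL` to use `b$labels`).
#' @param depth covering depth (default 5).
#' @param threshold normalized-rate mapping threshold (default 0.8,
#'   strict `>`).
#' @return a `MappingResult`: list with `raw` and `normalized` rate matrices
#'   (source x target), `mapped` logical matrix, `depth_used` per source
#'   class, `degenerate` flag per source class, `depth`, `threshold`.
#' @export
map_cell_types <- function(ps, b, labels = NULL, depth = 5, threshold = 0.8) {
  stopifnot(inherits(ps, "PanelSet"))
  if (depth < 1) stop("depth must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  labels <- resolve_labels(b, labels)
  empty <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(empty))
    stop("empty target class: ", paste(empty, collapse = ", "))
  src <- names(ps$panels)
  tgt <- levels(labels)
  raw <- matrix(NA_real_, length(src), length(tgt),
                dimnames = list(src, tgt))
  depth_used <- stats::setNames(integer(length(src)), src)
  for (k in src) {
    panel <- ps$panels[[k]]
    n_found <- length(match_panel(panel, rownames(b$x),
                                  error_on_empty = FALSE)$present)
    d_k <- min(depth, n_found)
    if (d_k < depth)
      warning("panel for class '", k, "' has only ", n_found,
              " genes in the target; using depth ", d_k, call. = FALSE)
    depth_used[k] <- d_k
    raw[k, ] <- if (n_found == 0) 0 else
      class_covering_rates(panel, b, labels, d = d_k)[tgt]
  }
  rng <- apply(raw, 1, function(r) diff(range(r)))
  degenerate <- rng == 0
  normalized <- raw
  for (k in src) {
    if (degenerate[k]) {
      normalized[k, ] <- NA_real_
    } else {
      normalized[k, ] <- (raw[k, ] - min(raw[k, ])) / rng[k]
    }
  }
  if (any(degenerate))
    warning("constant covering rates for source class(es): ",
            paste(src[degenerate], collapse = ", "),
            "; reported unmapped", call. = FALSE)
  mapped <- !is.na(normalized) & normalized > threshold
  structure(list(raw = raw, normalized = normalized, mapped = mapped,
                 depth_used = depth_used, degenerate = degenerate,
                 depth = depth, threshold = threshold),
            class = "MappingResult")
}

#' Flatten a mapping result to a table
#'
#' @param mr a `MappingResult` from [map_cell_types()].
#' @return data.frame with one row per (source, target) pair in a fixed
#'   order: source class, target class, raw rate, normalized rate, mapped
#'   flag.
#' @export
mapping_table <- function(mr) {
  stopifnot(inherits(mr, "MappingResult"))
  src <- rownames(mr$raw); tgt <- colnames(mr$raw)
  data.frame(
    source = rep(src, each = length(tgt)),
    target = rep(tgt, times = length(src)),
    raw_rate = as.vector(t(mr$raw)),
    normalized_rate = as.vector(t(mr$normalized)),
    mapped = as.vector(t(mr$mapped))
  )
}
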