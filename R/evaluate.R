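#' Within-panel-set redundancy
#'
#' The fraction of genes in the global (union) panel that appear in the
#' local panels of at least two classes. 0 means the per-class panels are
#' pairwise disjoint; 1 means every selected gene marks several classes.
#'
#' @param ps a `PanelSet` (at least one non-empty panel).
#' @return proportion in `[0, 1]`.
#' @export
redundancy <- function(ps) {
  stopifnot(inherits(ps, "PanelSet"))
  gene_lists <- lapply(ps$panels, `[[`, "genes")
  all_genes <- unlist(gene_lists, use.names = FALSE)
  if (!length(all_genes)) stop("all panels are empty")
  counts <- table(all_genes) # each panel lists a gene at most once
  sum(counts >= 2) / length(ps$global_panel)
}

#' Intersection proportion of two global panels
#'
#' The number of candidate-panel genes found in the reference panel, divided
#' by the reference panel size.
#'
#' @param candidate character vector of gene ids (or a `PanelSet`).
#' @param reference character vector of gene ids (or a `PanelSet`); must be
#'   non-empty.
#' @return proportion in `[0, 1]`.
#' @export
panel_intersection <- function(candidate, reference) {
  if (inherits(candidate, "PanelSet")) candidate <- candidate$global_panel
  if (inherits(reference, "PanelSet")) reference <- reference$global_panel
  candidate <- unique(as.character(candidate))
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("reference panel is empty")
  length(intersect(candidate, reference)) / length(reference)
}

#' Balanced accuracy
#'
#' Mean per-class recall (sensitivity) over the classes present in the truth
#' vector; classes with zero support are excluded from the mean and reported
#' in the `dropped` attribute.
#'
#' @param truth vector of true class labels.
#' @param predicted vector of predicted labels, same length.
#' @return value in `[0, 1]` with attribute `recalls` (named per-class).
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth (", length(truth), ") and predicted (", length(predicted),
         ") differ in length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(truth))
  if (!length(classes)) stop("no class with support")
  recalls <- vapply(classes, function(k) {
    idx <- truth == k
    mean(predicted[idx] == k)
  }, numeric(1))
  out <- mean(recalls)
  attr(out, "recalls") <- recalls
  out
}

#' Frequency-difference reference ranking
#'
#' A transparent one-gene-at-a-time baseline for size-matched comparisons:
#' ranks genes for class k by `m(g, k) - max_{l != k} m(g, l)` in descending
#' order (ties broken by gene id) and returns the top n. It scores each gene
#' in isolation, so unlike the covering objective it cannot trade off
#' overlap between classes.
#'
#' @param probs a `ClassProbabilities` from [estimate_probabilities()].
#' @param k target class name.
#' @param n panel size to return (1 <= n <= number of genes).
#' @return character vector of n gene ids.
#' @export
frequency_rank_reference <- function(probs, k, n) {
  stopifnot(inherits(probs, "ClassProbabilities"))
  if (!k %in% colnames(probs$m)) stop("unknown class: ", k)
  if (n < 1) stop("n must be >= 1")
  if (n > nrow(probs$m))
    stop("n (", n, ") exceeds number of genes (", nrow(probs$m), ")")
  off <- probs$m[, setdiff(colnames(probs$m), k), drop = FALSE]
  score <- probs$m[, k] - apply(off, 1, max)
  rownames(probs$m)[order(-score, rownames(probs$m))][seq_len(n)]
}
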