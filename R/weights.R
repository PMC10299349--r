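#' Estimate per-class expression probabilities
#'
#' For each gene g and class k, the empirical probability that g is expressed
#' (binarized indicator 1) among the cells of class k:
#' `m(g, k) = #\{c in S_k : u_g(c) = 1\} / |S_k|`. No shrinkage or
#' pseudocounts are applied.
#'
#' @param b a `BinaryMatrix` (see [binarize()]).
#' @param labels optional label vector overriding `b$labels`.
#' @return a `ClassProbabilities` list with `m` (genes x classes matrix of
#'   probabilities) and `class_sizes` (named integer vector).
#' @export
estimate_probabilities <- function(b, labels = NULL) {
  stopifnot(inherits(b, "BinaryMatrix"))
  labels <- resolve_labels(b, labels)
  sizes <- class_sizes_checked(labels)
  counts <- as.matrix(b$x %*% class_design(labels))
  m <- sweep(counts, 2, sizes, "/")
  structure(list(m = m, class_sizes = sizes), class = "ClassProbabilities")
}

resolve_labels <- function(b, labels) {
  labels <- labels %||% b$labels
  if (is.null(labels)) stop("cell labels are required")
  if (length(labels) != ncol(b$x))
    stop("labels length (", length(labels),
         ") does not match number of cells (", ncol(b$x), ")")
  if (anyNA(labels)) stop("labels contain NA")
  if (is.factor(labels)) labels else factor(labels)
}

class_sizes_checked <- function(labels) {
  sizes <- as.integer(table(labels))
  names(sizes) <- levels(labels)
  if (any(sizes == 0))
    stop("empty class: ", paste(names(sizes)[sizes == 0], collapse = ", "))
  sizes
}

# 0/1 cell x class indicator (works for K = 1 and avoids contrasts)
class_design <- function(labels) {
  vapply(levels(labels), function(l) as.numeric(labels == l),
         numeric(length(labels)))
}

#' Per-class means of log-normalized expression
#'
#' Counts are depth-normalized per cell to a fixed target sum (default
#' 10,000), transformed with `log(1 + x)`, and averaged within each class.
#' These class means feed the `lognorm_ratio` weight scheme; the covering
#' constraints always remain on the binarized data.
#'
#' @param m an `ExpressionMatrix`.
#' @param labels optional label vector overriding `m$labels`.
#' @param norm_target per-cell target sum (default 1e4).
#' @return a `ClassProbabilities`-shaped list (`m`, `class_sizes`) whose `m`
#'   holds non-negative class means, not probabilities.
#' @export
estimate_mean_lognorm <- function(m, labels = NULL, norm_target = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  b <- structure(list(x = m$counts, labels = m$labels), class = "BinaryMatrix")
  labels <- resolve_labels(b, labels)
  x <- m$counts
  depth <- Matrix::colSums(x)
  scale <- ifelse(depth > 0, norm_target / depth, 0)
  x@x <- log1p(x@x * rep.int(scale, diff(x@p)))
  sizes <- class_sizes_checked(labels)
  means <- sweep(as.matrix(x %*% class_design(labels)), 2, sizes, "/")
  structure(list(m = means, class_sizes = sizes),
            class = "ClassProbabilities")
}

#' Compute per-gene marker weights
#'
#' A small weight marks a gene as discriminative for the target class. The
#' ratio schemes divide a summary of off-class expression by the in-class
#' probability:
#' \itemize{
#'   \item `mean_ratio` (default): `w(g,k) = mean_{l != k} m(g,l) / m(g,k)`
#'     (off-class probabilities averaged over the `K - 1` other classes).
#'   \item `max_ratio`: the maximum off-class probability divided by `m(g,k)`.
#'   \item `lognorm_ratio`: `mean_ratio` applied to class means of
#'     log-normalized expression (pass the output of
#'     [estimate_mean_lognorm()]).
#'   \item `bonferroni`: the pooled off-class expression probability
#'     `P(U_g = 1 | Y != k)`, computed cell-weighted over all non-k cells.
#'   \item `log_complement`: `-log(1 - P(U_g = 1 | Y != k))`.
#' }
#' Zero denominators yield `+Inf` (such genes can never be candidates); a
#' perfectly specific gene (off-class probability 0, in-class > 0) gets
#' weight 0.
#'
#' @param probs a `ClassProbabilities` from [estimate_probabilities()] (or
#'   [estimate_mean_lognorm()] for `lognorm_ratio`).
#' @param scheme weight scheme (see above).
#' @param classes which classes to compute columns for (default all).
#' @return a `WeightTable` list with `w` (genes x classes matrix), `scheme`,
#'   and the `probs` used.
#' @export
compute_weights <- function(probs,
                            scheme = c("mean_ratio", "max_ratio",
                                       "lognorm_ratio", "bonferroni",
                                       "log_complement"),
                            classes = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(probs, "ClassProbabilities"))
  m <- probs$m
  K <- ncol(m)
  if (K < 2) stop("weight computation requires K >= 2 classes")
  classes <- classes %||% colnames(m)
  w <- matrix(NA_real_, nrow(m), length(classes),
              dimnames = list(rownames(m), classes))
  sizes <- probs$class_sizes
  for (k in classes) {
    off <- m[, setdiff(colnames(m), k), drop = FALSE]
    w[, k] <- switch(scheme,
      mean_ratio = ,
      lognorm_ratio = ratio_weight(rowMeans(off), m[, k]),
      max_ratio = ratio_weight(apply(off, 1, max), m[, k]),
      bonferroni = pooled_offclass(off, sizes[colnames(off)]),
      log_complement = -log1p(-pooled_offclass(off, sizes[colnames(off)]))
    )
  }
  structure(list(w = w, scheme = scheme, probs = probs),
            class = "WeightTable")
}

# off/self with the convention 0/0 = Inf (an unexpressed gene is never a
# candidate) and x/0 = Inf; off = 0, self > 0 gives a perfect weight of 0.
ratio_weight <- function(off, self) {
  out <- ifelse(self > 0, off / self, Inf)
  out[is.nan(out)] <- Inf
  out
}

pooled_offclass <- function(off, sizes) {
  as.vector(off %*% sizes) / sum(sizes)
}

#' Candidate gene set for a class
#'
#' Filters out genes that are either not discriminative (`w > max_weight`,
#' default cutoff 1) or too lowly expressed in the class
#' (`m < min_expr`, default 0.1). An empty candidate set is legal and left to
#' the caller.
#'
#' @param weights a `WeightTable`.
#' @param k class name.
#' @param min_expr minimum in-class expression probability (default 0.1).
#' @param max_weight weight cutoff (default 1).
#' @param probs optional `ClassProbabilities` for the expression filter;
#'   defaults to the probabilities stored in `weights`. Pass binarized
#'   probabilities explicitly when `weights` was built from log-normalized
#'   means.
#' @return character vector of candidate gene ids.
#' @export
candidate_set <- function(weights, k, min_expr = 0.1, max_weight = 1,
                          probs = NULL) {
  stopifnot(inherits(weights, "WeightTable"))
  probs <- probs %||% weights$probs
  if (!k %in% colnames(weights$w)) stop("unknown class: ", k)
  w <- weights$w[, k]
  m <- probs$m[, k]
  rownames(weights$w)[w <= max_weight & m >= min_expr]
}

#' Export a weight table as a flat data.frame
#'
#' @param weights a `WeightTable`.
#' @param min_expr,max_weight candidate filter thresholds (see
#'   [candidate_set()]).
#' @return data.frame with columns gene, class, m, w, candidate.
#' @export
weights_to_table <- function(weights, min_expr = 0.1, max_weight = 1) {
  w <- weights$w
  m <- weights$probs$m[, colnames(w), drop = FALSE]
  data.frame(
    gene = rep(rownames(w), times = ncol(w)),
    class = rep(colnames(w), each = nrow(w)),
    m = as.vector(m),
    w = as.vector(w),
    candidate = as.vector(w <= max_weight & m >= min_expr)
  )
}
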