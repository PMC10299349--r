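# Zero-inflated labeled count matrices with planted class-specific markers.
# The Bernoulli expression layer is the object of interest (binarization at
# theta = 0 recovers it exactly); positive counts are 1 + Poisson(lambda) so
# count magnitudes only matter to the log-normalized weight scheme.

#' Simulation configuration
#'
#' Describes a world of K cell classes, each with a block of planted marker
#' genes expressed with probability `p_in` in their own class and `p_out`
#' elsewhere, on top of `n_background_genes` background genes expressed with
#' probability `p_bg` everywhere. An optional sibling pair shares a fraction
#' `rho` of its markers (shared markers are expressed at `p_in` in both
#' siblings). `dropout` adds technical zeroing on top of the biological
#' Bernoulli layer.
#'
#' @param n_classes number of classes K (>= 2).
#' @param cells_per_class cells per class (scalar or length-K).
#' @param n_markers_per_class planted markers per class.
#' @param n_background_genes number of background genes.
#' @param p_in marker expression probability in its own class.
#' @param p_out marker expression probability in other classes.
#' @param p_bg background expression probability (scalar, or length-K vector
#'   to give classes distinct background profiles).
#' @param dropout extra per-entry zeroing probability in `[0, 1]`.
#' @param lambda_marker,lambda_bg Poisson means of the positive count law
#'   (`1 + Poisson(lambda)`) for markers and background genes.
#' @param sibling_pair optional integer pair of class indices sharing
#'   markers.
#' @param rho fraction of markers shared within the sibling pair.
#' @param seed integer seed; all randomness derives from it.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_classes = 3, cells_per_class = 200,
                       n_markers_per_class = 10, n_background_genes = 200,
                       p_in = 0.9, p_out = 0.05, p_bg = 0.3, dropout = 0,
                       lambda_marker = 2, lambda_bg = 1,
                       sibling_pair = NULL, rho = 0, seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  probs <- c(p_in, p_out, p_bg, dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_in <= p_out) stop("p_in must exceed p_out for planted identifiability")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (!is.null(sibling_pair)) {
    sibling_pair <- as.integer(sibling_pair)
    if (length(sibling_pair) != 2 || anyDuplicated(sibling_pair) ||
        any(sibling_pair < 1 | sibling_pair > n_classes))
      stop("sibling_pair must be two distinct class indices")
  }
  cells_per_class <- rep_len(as.integer(cells_per_class), n_classes)
  structure(list(n_classes = as.integer(n_classes),
                 cells_per_class = cells_per_class,
                 n_markers_per_class = as.integer(n_markers_per_class),
                 n_background_genes = as.integer(n_background_genes),
                 p_in = p_in, p_out = p_out, p_bg = p_bg, dropout = dropout,
                 lambda_marker = lambda_marker, lambda_bg = lambda_bg,
                 sibling_pair = sibling_pair, rho = rho,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Deterministic per-gene substream: adding genes never perturbs the draws of
# existing ones.
gene_stream_seed <- function(seed, gene_index) {
  as.integer((as.double(seed) * 48271 + gene_index * 16807) %% 2147483647)
}

#' Simulate a labeled zero-inflated count matrix with planted markers
#'
#' Entry (g, c) is nonzero with probability `p(g, class(c)) * (1 - dropout)`;
#' nonzero values are `1 + Poisson(lambda_g)`. Bit-identical output for
#' identical configs.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (an `ExpressionMatrix` with labels) and
#'   `truth` (a `SimTruth`: per-class planted marker ids, shared sibling
#'   markers, and realized per-(gene, class) expression frequencies).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  K <- cfg$n_classes
  classes <- sprintf("class%02d", seq_len(K))
  n_cells <- sum(cfg$cells_per_class)
  labels <- factor(rep(classes, cfg$cells_per_class), levels = classes)
  cell_names <- sprintf("cell%05d", seq_len(n_cells))

  nm <- cfg$n_markers_per_class
  marker_ids <- lapply(seq_len(K), function(k)
    sprintf("MK%02d_%03d", k, seq_len(nm)))
  bg_ids <- sprintf("BG_%04d", seq_len(cfg$n_background_genes))

  # per-(gene, class) expression probabilities
  p_bg <- rep_len(cfg$p_bg, K)
  owner <- c(rep(seq_len(K), each = nm), rep(0L, cfg$n_background_genes))
  genes <- c(unlist(marker_ids), bg_ids)
  P <- matrix(0, length(genes), K, dimnames = list(genes, classes))
  for (k in seq_len(K)) {
    P[owner == k, ] <- cfg$p_out
    P[owner == k, k] <- cfg$p_in
  }
  P[owner == 0L, ] <- matrix(p_bg, sum(owner == 0L), K, byrow = TRUE)

  shared <- character(0)
  truth_markers <- stats::setNames(marker_ids, classes)
  if (!is.null(cfg$sibling_pair) && cfg$rho > 0) {
    a <- cfg$sibling_pair[1]; b <- cfg$sibling_pair[2]
    n_shared <- round(cfg$rho * nm)
    if (n_shared > 0) {
      shared <- marker_ids[[a]][seq_len(n_shared)]
      P[shared, classes[b]] <- cfg$p_in
      # the sibling's own corresponding markers are retired to background
      retired <- marker_ids[[b]][seq_len(n_shared)]
      P[retired, ] <- matrix(p_bg, n_shared, K, byrow = TRUE)
      truth_markers[[classes[b]]] <-
        c(shared, setdiff(marker_ids[[b]], retired))
      truth_markers[[classes[a]]] <- marker_ids[[a]]
    }
  }

  lambda <- ifelse(owner > 0, cfg$lambda_marker, cfg$lambda_bg)
  class_idx <- as.integer(labels)
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    set.seed(gene_stream_seed(cfg$seed, gi))
    p_cell <- P[gi, class_idx] * (1 - cfg$dropout)
    on <- stats::runif(n_cells) < p_cell
    vals <- integer(n_cells)
    n_on <- sum(on)
    if (n_on) vals[on] <- 1L + stats::rpois(n_on, lambda[gi])
    rows[[gi]] <- vals
  }
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(genes, cell_names)
  m <- expression_matrix(counts, labels = stats::setNames(labels, cell_names))

  realized <- estimate_probabilities(binarize(m, 0), labels)$m
  truth <- structure(list(markers = truth_markers, shared = shared,
                          realized_freq = realized,
                          background = bg_ids, config = cfg),
                     class = "SimTruth")
  list(matrix = m, truth = truth)
}

#' Sibling-class scenario
#'
#' Convenience wrapper around [simulate_counts()] planting a pair of classes
#' that share a fraction `rho` of their markers — a controlled redundancy
#' trap. With `rho = 0` this reduces exactly to [simulate_counts()].
#'
#' @param cfg a [sim_config()]; its `sibling_pair`/`rho` are overridden.
#' @param pair integer pair of class indices (default classes 1 and 2).
#' @param rho shared marker fraction.
#' @return as [simulate_counts()].
#' @export
sibling_scenario <- function(cfg, pair = c(1L, 2L), rho = 0.5) {
  cfg2 <- sim_config(n_classes = cfg$n_classes,
                     cells_per_class = cfg$cells_per_class,
                     n_markers_per_class = cfg$n_markers_per_class,
                     n_background_genes = cfg$n_background_genes,
                     p_in = cfg$p_in, p_out = cfg$p_out, p_bg = cfg$p_bg,
                     dropout = cfg$dropout,
                     lambda_marker = cfg$lambda_marker,
                     lambda_bg = cfg$lambda_bg,
                     sibling_pair = if (rho > 0) pair else NULL, rho = rho,
                     seed = cfg$seed)
  simulate_counts(cfg2)
}
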