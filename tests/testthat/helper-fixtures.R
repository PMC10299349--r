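# Shared fixtures, all built in code.

# The ABC micro-fixture: genes A, B, C over four cells of one class.
# A is expressed in c1-c3, B in c2-c4, C in c1 and c4; every cell expresses
# exactly two of the three genes.
abc_matrix <- function() {
  u <- rbind(A = c(1, 1, 1, 0),
             B = c(0, 1, 1, 1),
             C = c(1, 0, 0, 1))
  colnames(u) <- paste0("c", 1:4)
  u
}

abc_weights <- function() c(A = 0.3, B = 0.3, C = 0.5)

# Random covering instance within the brute-force oracle's comfort zone.
random_instance <- function(n_genes = NULL, n_cells = NULL) {
  ng <- n_genes %||% sample(3:12, 1)
  nc <- n_cells %||% sample(5:40, 1)
  u <- matrix(rbinom(ng * nc, 1, runif(1, 0.2, 0.7)), ng, nc,
              dimnames = list(sprintf("g%02d", seq_len(ng)),
                              sprintf("c%02d", seq_len(nc))))
  w <- round(runif(ng, 0.01, 1.5), 3)
  names(w) <- rownames(u)
  list(u = u, w = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inf-safe monotonicity helpers (infeasible solves carry objective Inf and
# Inf - Inf is NaN under diff()).
nondecreasing <- function(v) all(diff(pmin(v, 1e12)) >= -1e-9)
nonincreasing <- function(v) all(diff(pmin(v, 1e12)) <= 1e-9)

# Small labeled expression matrix with obvious per-class markers:
# gene Mk is expressed in every cell of class k only; gene UB everywhere.
toy_labeled_matrix <- function(cells_per_class = 4, K = 3) {
  classes <- paste0("k", seq_len(K))
  labels <- rep(classes, each = cells_per_class)
  n <- length(labels)
  counts <- matrix(0, K + 1, n,
                   dimnames = list(c(paste0("M", seq_len(K)), "UB"),
                                   paste0("c", seq_len(n))))
  for (k in seq_len(K)) counts[k, labels == classes[k]] <- 2
  counts["UB", ] <- 1
  expression_matrix(counts, labels = labels)
}

fast_config <- function(...) cover_config(...)
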