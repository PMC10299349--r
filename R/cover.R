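# Core covering solvers. All three back-ends share one input convention:
# `u` is the binarized expression restricted to the cells of the target class
# (rows = candidate genes, columns = class cells), `w` the candidate weights.

as_cover_matrix <- function(u) {
  if (inherits(u, "BinaryMatrix")) u <- u$x
  u <- as.matrix(u)
  storage.mode(u) <- "integer"
  if (is.null(rownames(u)) && nrow(u))
    rownames(u) <- paste0("g", seq_len(nrow(u)))
  if (is.null(colnames(u)) && ncol(u))
    colnames(u) <- paste0("c", seq_len(ncol(u)))
  u
}

# ceiling((1 - alpha) * n) robust to floating fuzz like 0.75 * 4 = 3.0000...4
required_cells <- function(n, alpha) {
  as.integer(ceiling((1 - alpha) * n - 1e-9))
}

#' Check feasibility of a covering instance
#'
#' A class can be covered at depth `d` and rate `1 - alpha` by SOME panel iff
#' it is covered by the full candidate set: `max_coverable`, the number of
#' class cells expressing at least `d` candidate genes, must reach
#' `n_required = ceiling((1 - alpha) |S_k|)`.
#'
#' @param u binary candidate-genes x class-cells matrix (or `BinaryMatrix`).
#' @param d covering depth.
#' @param alpha tolerated uncovered fraction.
#' @return list with `feasible`, `max_coverable`, `n_required`, and
#'   `max_feasible_rate` (the largest covering rate any panel can achieve).
#' @export
feasibility_check <- function(u, d, alpha) {
  u <- as_cover_matrix(u)
  n <- ncol(u)
  depth_all <- if (nrow(u)) colSums(u) else rep(0L, n)
  max_coverable <- sum(depth_all >= d)
  n_required <- required_cells(n, alpha)
  list(feasible = max_coverable >= n_required,
       max_coverable = max_coverable,
       n_required = n_required,
       max_feasible_rate = if (n > 0) max_coverable / n else 0)
}

cover_solution <- function(class_name, u, w, sel_genes, status, config,
                           diagnostics = list()) {
  d <- config$depth
  n <- ncol(u)
  if (length(sel_genes)) {
    depth <- colSums(u[sel_genes, , drop = FALSE])
  } else {
    depth <- rep(0L, n)
  }
  covered <- depth >= d
  names(covered) <- colnames(u)
  rate <- if (n > 0) sum(covered) / n else NA_real_
  # present genes by ascending weight, ties by gene id
  ord <- order(w[sel_genes], sel_genes)
  sel_genes <- sel_genes[ord]
  panel <- marker_panel(class_name, sel_genes, unname(w[sel_genes]), config,
                        achieved_rate = if (status == "infeasible") NA_real_
                                        else rate,
                        solver_status = status, diagnostics = diagnostics)
  structure(list(panel = panel, covered = covered,
                 n_required = required_cells(n, config$alpha)),
            class = "CoverSolution")
}

infeasible_solution <- function(class_name, u, w, config, feas) {
  cover_solution(class_name, u, w, character(0), "infeasible", config,
                 diagnostics = list(
                   max_feasible_rate = feas$max_feasible_rate,
                   max_coverable = feas$max_coverable,
                   n_required = feas$n_required,
                   hint = "raise alpha or lower depth"))
}

validate_cover_inputs <- function(u, w, forced) {
  if (is.null(names(w))) {
    if (length(w) != nrow(u)) stop("weights must be named or match nrow(u)")
    names(w) <- rownames(u)
  }
  missing <- setdiff(rownames(u), names(w))
  if (length(missing)) stop("weights missing for genes: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  w <- w[rownames(u)]
  if (any(w < 0)) stop("weights must be non-negative")
  bad <- setdiff(forced, rownames(u))
  if (length(bad))
    stop("initial panel gene(s) not in candidate set: ",
         paste(bad, collapse = ", "))
  w
}

#' Solve the minimal-weight partial set multi-cover for one class
#'
#' Minimizes the total weight of selected genes subject to: at least
#' `n_required = ceiling((1 - alpha) |S_k|)` class cells each express at
#' least `d` selected genes. The default back-end is an exact branch and
#' bound (status `optimal`; on hitting the node/time budget the best
#' incumbent is returned with status `gap_reported`). The achieved covering
#' rate is always recomputed from the returned panel, never trusted from the
#' solver.
#'
#' @param u binary candidate-genes x class-cells matrix (or `BinaryMatrix`)
#'   restricted to the target class cells and candidate genes.
#' @param w non-negative candidate weights, named by gene (infinite-weight
#'   genes are dropped).
#' @param config a [cover_config()]; `depth`, `alpha`, `solver`,
#'   `time_limit` and `node_limit` are honoured here.
#' @param class_name label stored in the resulting panel.
#' @param forced genes that must be part of the panel (nested expansion).
#' @return a `CoverSolution`: list with `panel` (a `MarkerPanel`), `covered`
#'   (named logical per cell) and `n_required`.
#' @export
solve_cover <- function(u, w, config, class_name = "class",
                        forced = character(0)) {
  u <- as_cover_matrix(u)
  w <- validate_cover_inputs(u, w, forced)
  keep <- is.finite(w)
  if (any(!keep & rownames(u) %in% forced))
    stop("initial panel gene(s) have infinite weight")
  u0 <- u; w0 <- w
  u <- u[keep, , drop = FALSE]; w <- w[keep]
  feas <- feasibility_check(u, config$depth, config$alpha)
  if (!feas$feasible)
    return(infeasible_solution(class_name, u0, w0, config, feas))
  if (config$solver == "brute_force")
    return(brute_force_cover(u, w, config, class_name, forced))
  if (config$solver == "greedy")
    return(greedy_cover(u, w, config, class_name, forced))

  # deterministic gene order: ascending weight, ties by gene id
  ord <- order(w, rownames(u))
  u <- u[ord, , drop = FALSE]; w <- w[ord]
  g_ids <- rownames(u)

  inc <- greedy_cover(u, w, config, class_name, forced)
  inc_obj <- if (inc$panel$solver_status == "infeasible") Inf else
    inc$panel$objective
  inc_idx <- match(inc$panel$genes, g_ids)

  res <- .bb_cover(t(u), unname(w), config$depth, feas$n_required,
                   g_ids %in% forced, inc_obj,
                   as.integer(inc_idx), config$node_limit, config$time_limit)
  if (res$status == "infeasible") # cannot happen after feasibility_check,
    return(infeasible_solution(class_name, u0, w0, config, feas)) # but safe
  sel <- g_ids[res$selected]
  diag <- list(nodes = res$nodes)
  if (res$status == "gap_reported")
    diag$gap <- NA_real_ # incumbent returned without a proven bound
  cover_solution(class_name, u, w, sel, res$status, config, diag)
}

#' Brute-force covering oracle
#'
#' Exhaustively enumerates all gene subsets (containing `forced`) and returns
#' a global minimum-objective feasible solution; ties are broken by smaller
#' objective, then smaller cardinality, then enumeration order over genes
#' sorted by (weight, gene id). Exponential: refuses more than `cap` genes.
#' Exists to certify [solve_cover()] on small instances.
#'
#' @inheritParams solve_cover
#' @param cap hard limit on the number of candidate genes (default 20).
#' @return a `CoverSolution`.
#' @export
brute_force_cover <- function(u, w, config, class_name = "class",
                              forced = character(0), cap = 20) {
  u <- as_cover_matrix(u)
  w <- validate_cover_inputs(u, w, forced)
  keep <- is.finite(w)
  u <- u[keep, , drop = FALSE]; w <- w[keep]
  n_genes <- nrow(u)
  if (n_genes > cap)
    stop("brute_force_cover: ", n_genes, " genes exceeds cap ", cap)
  feas <- feasibility_check(u, config$depth, config$alpha)
  if (!feas$feasible)
    return(infeasible_solution(class_name, u, w, config, feas))
  ord <- order(w, rownames(u))
  u <- u[ord, , drop = FALSE]; w <- w[ord]
  g_ids <- rownames(u)
  forced_mask <- sum(bitwShiftL(1, which(g_ids %in% forced) - 1L))
  d <- config$depth; n_req <- feas$n_required

  best <- list(obj = Inf, card = Inf, mask = NA_integer_)
  masks_all <- seq(0L, 2^n_genes - 1L)
  ut <- t(u) # cells x genes
  for (chunk in split(masks_all, ceiling(seq_along(masks_all) / 65536))) {
    Z <- vapply(seq_len(n_genes) - 1L,
                function(b) bitwAnd(chunk, bitwShiftL(1L, b)) > 0L,
                logical(length(chunk)))
    Z <- matrix(Z, nrow = length(chunk))
    ok_forced <- bitwAnd(chunk, forced_mask) == forced_mask
    depth <- Z %*% t(ut) # subsets x cells
    covered <- rowSums(depth >= d)
    obj <- as.vector(Z %*% w)
    card <- rowSums(Z)
    feasible <- ok_forced & covered >= n_req
    if (any(feasible)) {
      o <- obj[feasible]; k <- card[feasible]; m <- chunk[feasible]
      i <- order(o, k)[1]
      if (o[i] < best$obj - 1e-12 ||
          (abs(o[i] - best$obj) <= 1e-12 && k[i] < best$card)) {
        best <- list(obj = o[i], card = k[i], mask = m[i])
      }
    }
  }
  if (!is.finite(best$obj))
    return(infeasible_solution(class_name, u, w, config, feas))
  sel <- g_ids[bitwAnd(best$mask, bitwShiftL(1L, seq_len(n_genes) - 1L)) > 0L]
  cover_solution(class_name, u, w, sel, "optimal", config,
                 diagnostics = list(oracle = "exhaustive"))
}

#' Greedy covering heuristic
#'
#' Iteratively adds the gene with the best ratio of newly satisfied coverage
#' demand to weight, where demand is counted over the `n_required`
#' easiest-to-cover cells given the current selection. Feasible output always
#' satisfies the covering constraint; the objective is an upper bound on the
#' exact optimum.
#'
#' @inheritParams solve_cover
#' @return a `CoverSolution` with status `greedy` (or `infeasible`).
#' @export
greedy_cover <- function(u, w, config, class_name = "class",
                         forced = character(0)) {
  u <- as_cover_matrix(u)
  w <- validate_cover_inputs(u, w, forced)
  keep <- is.finite(w)
  u <- u[keep, , drop = FALSE]; w <- w[keep]
  feas <- feasibility_check(u, config$depth, config$alpha)
  if (!feas$feasible)
    return(infeasible_solution(class_name, u, w, config, feas))
  ord <- order(w, rownames(u))
  u <- u[ord, , drop = FALSE]; w <- w[ord]
  d <- config$depth; n_req <- feas$n_required
  g_ids <- rownames(u)
  potential <- colSums(u) # depth if everything were selected
  selected <- g_ids %in% forced
  depth <- if (any(selected)) colSums(u[selected, , drop = FALSE])
           else rep(0L, ncol(u))
  repeat {
    covered <- sum(depth >= d)
    if (covered >= n_req) break
    coverable <- potential >= d
    deficit <- pmax(d - depth, 0L)
    # the n_required easiest-to-cover coverable cells define current demand
    targets <- which(coverable)[order(deficit[coverable])][seq_len(n_req)]
    open <- targets[deficit[targets] > 0L]
    cand <- which(!selected)
    if (!length(cand) || !length(open)) {
      return(infeasible_solution(class_name, u, w, config, feas))
    }
    gain <- rowSums(u[cand, open, drop = FALSE] > 0L)
    helpful <- gain > 0
    if (!any(helpful))
      return(infeasible_solution(class_name, u, w, config, feas))
    score <- ifelse(w[cand] > 0, gain / w[cand], ifelse(gain > 0, Inf, 0))
    pick <- cand[helpful][order(-score[helpful], w[cand][helpful])][1]
    selected[pick] <- TRUE
    depth <- depth + u[pick, ]
  }
  cover_solution(class_name, u, w, g_ids[selected], "greedy", config)
}

#' Expand a panel to a larger covering depth, keeping it nested
#'
#' Re-solves the cover at depth `config$depth` with the additional constraint
#' that every gene of the initial panel stays selected, so the result is a
#' superset of the initial panel. The new depth must be at least the depth
#' the initial panel was fitted at; `alpha` may stay or change.
#'
#' @inheritParams solve_cover
#' @param initial character vector of gene ids (or a `MarkerPanel`) that must
#'   be contained in the result; all must be present among the rows of `u`.
#' @return a `CoverSolution`.
#' @export
nested_expand <- function(u, w, config, initial, class_name = "class") {
  if (inherits(initial, "MarkerPanel")) {
    if (!is.null(initial$config) && config$depth < initial$config$depth)
      stop("expansion depth ", config$depth,
           " is smaller than the initial panel depth ", initial$config$depth)
    class_name <- initial$class_name
    initial <- initial$genes
  }
  solve_cover(u, w, config, class_name = class_name, forced = initial)
}

#' Fit covering marker panels for every class
#'
#' Runs the full per-class pipeline: binarize at `config$theta`, estimate
#' per-class expression probabilities, compute weights under
#' `config$scheme`, filter to the candidate set
#' (`w <= max_weight`, `m >= min_expr`), check feasibility and solve the
#' cover. Per-class failures (infeasibility, empty candidate sets) are
#' reported in the corresponding panel, never aborting the other classes.
#'
#' @param m an `ExpressionMatrix` with labels (K >= 2 classes).
#' @param config a [cover_config()].
#' @param labels optional label override.
#' @return a `PanelSet`.
#' @export
fit_all_classes <- function(m, config = cover_config(), labels = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  b <- binarize(m, config$theta)
  labels <- resolve_labels(b, labels)
  if (nlevels(labels) < 2)
    stop("at least 2 classes are required, got ", nlevels(labels))
  probs <- estimate_probabilities(b, labels)
  wt <- if (config$scheme == "lognorm_ratio") {
    compute_weights(estimate_mean_lognorm(m, labels, config$norm_target),
                    scheme = "lognorm_ratio")
  } else {
    compute_weights(probs, scheme = config$scheme)
  }
  panels <- lapply(levels(labels), function(k) {
    res <- tryCatch({
      cand <- candidate_set(wt, k, min_expr = config$min_expr,
                            max_weight = config$max_weight, probs = probs)
      uk <- binary_submatrix(b, cand, labels == k)
      sol <- solve_cover(uk, wt$w[cand, k], config, class_name = k)
      sol$panel
    }, error = function(e) {
      marker_panel(k, character(0), numeric(0), config,
                   solver_status = "infeasible",
                   diagnostics = list(error = conditionMessage(e)))
    })
    res
  })
  panel_set(panels)
}

binary_submatrix <- function(b, genes, cell_mask) {
  x <- b$x[genes, cell_mask, drop = FALSE]
  u <- as.matrix(x)
  storage.mode(u) <- "integer"
  u
}

#' Expand every panel in a set to a larger depth
#'
#' @param m the `ExpressionMatrix` the panels were fitted on (or comparable
#'   data with the same classes).
#' @param ps a `PanelSet` of initial panels.
#' @param depth new covering depth (>= each panel's fitted depth).
#' @param alpha optional new alpha; defaults to each panel's fitted alpha.
#' @param labels optional label override.
#' @return a `PanelSet` of expanded panels (supersets of the initial ones).
#' @export
expand_all_classes <- function(m, ps, depth, alpha = NULL, labels = NULL) {
  stopifnot(inherits(ps, "PanelSet"))
  base_cfg <- ps$panels[[1]]$config %||% cover_config()
  cfg0 <- cover_config(depth = depth, alpha = alpha %||% base_cfg$alpha,
                       theta = base_cfg$theta, scheme = base_cfg$scheme,
                       min_expr = base_cfg$min_expr,
                       max_weight = base_cfg$max_weight,
                       solver = base_cfg$solver,
                       time_limit = base_cfg$time_limit,
                       node_limit = base_cfg$node_limit,
                       seed = base_cfg$seed, norm_target = base_cfg$norm_target)
  b <- binarize(m, cfg0$theta)
  labels <- resolve_labels(b, labels)
  probs <- estimate_probabilities(b, labels)
  wt <- if (cfg0$scheme == "lognorm_ratio") {
    compute_weights(estimate_mean_lognorm(m, labels, cfg0$norm_target),
                    scheme = "lognorm_ratio")
  } else {
    compute_weights(probs, scheme = cfg0$scheme)
  }
  panels <- lapply(ps$panels, function(p) {
    cfg <- cfg0
    if (!is.null(p$config)) {
      cfg$alpha <- alpha %||% p$config$alpha
      if (depth < p$config$depth)
        stop("expansion depth ", depth, " below fitted depth ",
             p$config$depth, " for class ", p$class_name)
    }
    tryCatch({
      cand <- union(candidate_set(wt, p$class_name, min_expr = cfg$min_expr,
                                  max_weight = cfg$max_weight, probs = probs),
                    p$genes)
      missing <- setdiff(p$genes, rownames(b$x))
      if (length(missing))
        stop("initial panel gene(s) absent from data: ",
             paste(missing, collapse = ", "))
      uk <- binary_submatrix(b, cand, labels == p$class_name)
      sol <- nested_expand(uk, wt$w[cand, p$class_name], cfg, p)
      sol$panel
    }, error = function(e) {
      marker_panel(p$class_name, character(0), numeric(0), cfg,
                   solver_status = "infeasible",
                   diagnostics = list(error = conditionMessage(e)))
    })
  })
  panel_set(panels)
}
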