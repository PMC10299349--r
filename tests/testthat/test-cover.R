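test_that("feasibility_check counts coverable cells and required cells", {
  u <- abc_matrix()
  # every cell expresses exactly 2 of {A,B,C}
  f <- feasibility_check(u, d = 2, alpha = 0)
  expect_true(f$feasible)
  expect_equal(f$max_coverable, 4)
  expect_equal(f$n_required, 4L)
  # depth 3 is unreachable for every cell
  f3 <- feasibility_check(u, d = 3, alpha = 0)
  expect_false(f3$feasible)
  expect_equal(f3$max_feasible_rate, 0)
  # a cell expressing nothing makes alpha = 0 infeasible at d = 1
  u2 <- cbind(u, c5 = c(0, 0, 0))
  f1 <- feasibility_check(u2, d = 1, alpha = 0)
  expect_false(f1$feasible)
  expect_equal(f1$max_feasible_rate, 4 / 5)
  expect_true(feasibility_check(u2, d = 1, alpha = 0.2)$feasible)
})

test_that("n_required uses the ceiling of (1 - alpha) |S_k|", {
  u <- abc_matrix()
  expect_equal(feasibility_check(u, 1, 0.25)$n_required, 3L)
  expect_equal(feasibility_check(u, 1, 0.5)$n_required, 2L)
  expect_equal(feasibility_check(u, 1, 0.1)$n_required, 4L) # ceil(3.6)
})

test_that("the ABC fixture yields the enumerated optima", {
  u <- abc_matrix(); w <- abc_weights()
  cases <- list(list(d = 1, a = 0,   obj = 0.6, genes = c("A", "B")),
                list(d = 2, a = 0,   obj = 1.1, genes = c("A", "B", "C")),
                list(d = 2, a = 0.5, obj = 0.6, genes = c("A", "B")))
  for (cs in cases) {
    cfg <- cover_config(depth = cs$d, alpha = cs$a)
    sol <- solve_cover(u, w, cfg)
    expect_equal(sol$panel$objective, cs$obj)
    expect_equal(sol$panel$solver_status, "optimal")
    expect_setequal(sol$panel$genes, cs$genes)
    oracle <- brute_force_cover(u, w, cfg)
    expect_equal(oracle$panel$objective, cs$obj)
  }
  # d=2, alpha=0.5 covers exactly c2 and c3 at depth 2
  sol <- solve_cover(u, w, cover_config(depth = 2, alpha = 0.5))
  expect_equal(sol$covered, c(c1 = FALSE, c2 = TRUE, c3 = TRUE, c4 = FALSE))
})

test_that("infeasible and degenerate instances report, never crash", {
  u <- abc_matrix(); w <- abc_weights()
  cfg <- cover_config(depth = 3, alpha = 0)
  for (fn in list(solve_cover, brute_force_cover, greedy_cover)) {
    sol <- fn(u, w, cfg)
    expect_equal(sol$panel$solver_status, "infeasible")
    expect_equal(sol$panel$diagnostics$max_feasible_rate, 0)
  }
  # empty candidate set
  empty <- u[integer(0), , drop = FALSE]
  sol <- solve_cover(empty, numeric(0), cover_config(depth = 1, alpha = 0))
  expect_equal(sol$panel$solver_status, "infeasible")
})

test_that("a dominant singleton is selected by every back-end", {
  u <- rbind(star = rep(1, 5), other = c(1, 0, 0, 0, 0))
  colnames(u) <- paste0("c", 1:5)
  w <- c(star = 0.2, other = 0.1)
  for (solver in c("ilp", "greedy", "brute_force")) {
    sol <- solve_cover(u, w, cover_config(depth = 1, alpha = 0,
                                          solver = solver))
    expect_equal(sol$panel$genes, "star")
    expect_equal(sol$panel$objective, 0.2)
    expect_equal(sol$panel$achieved_rate, 1)
  }
})

test_that("solver matches the brute-force oracle on random instances", {
  set.seed(20240901)
  for (i in 1:60) {
    inst <- random_instance()
    d <- sample(1:3, 1)
    a <- sample(c(0, 0.1, 0.25), 1)
    cfg <- cover_config(depth = d, alpha = a)
    sol <- solve_cover(inst$u, inst$w, cfg)
    oracle <- brute_force_cover(inst$u, inst$w, cfg)
    if (oracle$panel$solver_status == "infeasible") {
      expect_equal(sol$panel$solver_status, "infeasible")
    } else {
      expect_equal(sol$panel$solver_status, "optimal")
      expect_equal(sol$panel$objective, oracle$panel$objective,
                   tolerance = 1e-9)
      # recomputed rate honours the covering constraint
      expect_gte(sol$panel$achieved_rate, 1 - a)
      # greedy never beats the optimum
      g <- greedy_cover(inst$u, inst$w, cfg)
      expect_gte(g$panel$objective, oracle$panel$objective - 1e-9)
      expect_gte(g$panel$achieved_rate, 1 - a)
    }
  }
})

test_that("objective is monotone in depth and alpha", {
  set.seed(77)
  for (i in 1:15) {
    inst <- random_instance(n_genes = 8, n_cells = 20)
    objs <- matrix(NA_real_, 3, 3)
    alphas <- c(0, 0.1, 0.25)
    for (d in 1:3) for (j in 1:3) {
      sol <- solve_cover(inst$u, inst$w,
                         cover_config(depth = d, alpha = alphas[j]))
      objs[d, j] <- if (sol$panel$solver_status == "infeasible") Inf
                    else sol$panel$objective
    }
    for (j in 1:3) expect_true(nondecreasing(objs[, j])) # d up
    for (d in 1:3) expect_true(nonincreasing(objs[d, ]))  # alpha up
  }
})

test_that("nested expansion returns supersets dominating the free optimum", {
  u <- abc_matrix(); w <- abc_weights()
  s1 <- solve_cover(u, w, cover_config(depth = 1, alpha = 0.25))
  expect_equal(s1$panel$genes, "A")
  expect_equal(s1$panel$objective, 0.3)
  s2 <- nested_expand(u, w, cover_config(depth = 2, alpha = 0.5), s1$panel)
  expect_setequal(s2$panel$genes, c("A", "B"))
  expect_equal(s2$panel$objective, 0.6)
  # re-expanding at the same depth keeps an already-optimal panel
  s3 <- nested_expand(u, w, cover_config(depth = 2, alpha = 0.5), s2$panel)
  expect_setequal(s3$panel$genes, s2$panel$genes)
  # empty initial panel reduces to the unconstrained solve
  s4 <- nested_expand(u, w, cover_config(depth = 2, alpha = 0), character(0))
  expect_equal(s4$panel$objective,
               solve_cover(u, w, cover_config(depth = 2, alpha = 0))$panel$objective)
  # unknown initial gene is a config-mismatch error
  expect_error(nested_expand(u, w, cover_config(depth = 2, alpha = 0), "Z"),
               "not in candidate set")
  # expansion below the fitted depth is rejected
  expect_error(nested_expand(u, w, cover_config(depth = 1, alpha = 0.5),
                             s2$panel),
               "smaller than the initial panel depth")
})

test_that("nested expansion properties hold on random instances", {
  set.seed(909)
  n_checked <- 0
  while (n_checked < 20) {
    inst <- random_instance(n_genes = 8, n_cells = 20)
    cfg1 <- cover_config(depth = 1, alpha = 0.25)
    s1 <- solve_cover(inst$u, inst$w, cfg1)
    if (s1$panel$solver_status == "infeasible") next
    cfg2 <- cover_config(depth = 2, alpha = 0.25)
    free <- solve_cover(inst$u, inst$w, cfg2)
    if (free$panel$solver_status == "infeasible") next
    nested <- nested_expand(inst$u, inst$w, cfg2, s1$panel)
    expect_true(all(s1$panel$genes %in% nested$panel$genes))
    expect_gte(nested$panel$objective, free$panel$objective - 1e-9)
    expect_gte(nested$panel$achieved_rate, 0.75)
    # oracle with the same superset constraint agrees
    oracle <- brute_force_cover(inst$u, inst$w, cfg2,
                                forced = s1$panel$genes)
    expect_equal(nested$panel$objective, oracle$panel$objective,
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("cells expressing no candidate gene still consume the alpha budget", {
  u <- cbind(abc_matrix(), c5 = c(0, 0, 0))
  w <- abc_weights()
  # 5 cells, alpha = 0.2 -> n_required = 4; the dead cell uses up the budget,
  # so all four live cells must be covered (same panel as alpha = 0 on 4)
  sol <- solve_cover(u, w, cover_config(depth = 1, alpha = 0.2))
  expect_equal(sol$n_required, 4L)
  expect_equal(sol$panel$objective, 0.6)
  expect_equal(sol$panel$achieved_rate, 0.8)
})

test_that("fit_all_classes recovers planted markers per class", {
  sim <- simulate_counts(sim_config(n_classes = 3, cells_per_class = 60,
                                    n_markers_per_class = 5,
                                    n_background_genes = 40, seed = 42))
  ps <- fit_all_classes(sim$matrix, cover_config(depth = 2, alpha = 0.05))
  expect_length(ps$panels, 3)
  for (k in names(ps$panels)) {
    p <- ps$panels[[k]]
    expect_equal(p$solver_status, "optimal")
    expect_true(all(p$genes %in% sim$truth$markers[[k]]))
    expect_gte(p$achieved_rate, 0.95)
  }
})

test_that("fit_all_classes needs K >= 2 and survives hopeless classes", {
  m1 <- toy_labeled_matrix(K = 3)
  one <- expression_matrix(as.matrix(m1$counts),
                           labels = rep("k", ncol(m1$counts)))
  expect_error(fit_all_classes(one), "at least 2 classes")
  # two generatively identical classes: no persistent discriminative gene
  set.seed(12)
  counts <- matrix(rbinom(40 * 30, 1, 0.4), 40, 30,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("c%02d", 1:30)))
  twin <- expression_matrix(counts, labels = rep(c("t1", "t2"), 15))
  ps <- fit_all_classes(twin, cover_config(depth = 3, alpha = 0))
  expect_length(ps$panels, 2) # reported, not crashed
  expect_true(all(vapply(ps$panels, function(p)
    p$solver_status %in% c("optimal", "infeasible"), logical(1))))
})

test_that("lognorm scheme weights change ordering but constraints stay binary", {
  sim <- simulate_counts(sim_config(n_classes = 2, cells_per_class = 40,
                                    n_markers_per_class = 4,
                                    n_background_genes = 20,
                                    lambda_marker = 4, seed = 9))
  ps <- fit_all_classes(sim$matrix,
                        cover_config(depth = 2, alpha = 0.05,
                                     scheme = "lognorm_ratio"))
  for (k in names(ps$panels)) {
    expect_equal(ps$panels[[k]]$solver_status, "optimal")
    expect_gte(ps$panels[[k]]$achieved_rate, 0.95)
  }
})

test_that("expand_all_classes grows fitted panels into nested supersets", {
  sim <- simulate_counts(sim_config(n_classes = 2, cells_per_class = 50,
                                    n_markers_per_class = 6,
                                    n_background_genes = 30, seed = 5))
  ps1 <- fit_all_classes(sim$matrix, cover_config(depth = 1, alpha = 0.05))
  ps2 <- expand_all_classes(sim$matrix, ps1, depth = 3)
  for (k in names(ps1$panels)) {
    expect_true(all(ps1$panels[[k]]$genes %in% ps2$panels[[k]]$genes))
    expect_gte(ps2$panels[[k]]$achieved_rate, 0.95)
  }
})
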