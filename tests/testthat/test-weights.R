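make_binary <- function(u, labels) {
  m <- expression_matrix(u, gene_ids = rownames(u), cell_ids = colnames(u),
                         labels = labels)
  binarize(m, 0)
}

test_that("estimate_probabilities matches hand counts on the ABC fixture", {
  u <- cbind(abc_matrix(), k2_1 = c(0, 0, 1), k2_2 = c(1, 0, 0))
  b <- make_binary(u, c(rep("k", 4), "k2", "k2"))
  probs <- estimate_probabilities(b)
  expect_equal(probs$m[, "k"], c(A = 0.75, B = 0.75, C = 0.5))
  expect_equal(probs$m[, "k2"], c(A = 0.5, B = 0, C = 0.5))
  expect_equal(probs$class_sizes, c(k = 4L, k2 = 2L))
  # frequencies times class size are integer expressing-cell counts
  expect_equal(probs$m %*% diag(probs$class_sizes) %% 1,
               matrix(0, 3, 2), ignore_attr = TRUE)
})

test_that("empty classes are rejected by name", {
  u <- abc_matrix()
  b <- make_binary(u, rep("k", 4))
  lab <- factor(rep("k", 4), levels = c("k", "ghost"))
  expect_error(estimate_probabilities(b, lab), "ghost")
})

test_that("mean/max ratio weights follow the off-class/in-class formulas", {
  m <- matrix(c(0.8, 0.2, 0.4), 1, 3,
              dimnames = list("g", c("k", "l1", "l2")))
  probs <- structure(list(m = m, class_sizes = c(k = 10L, l1 = 10L, l2 = 10L)),
                     class = "ClassProbabilities")
  expect_equal(compute_weights(probs, "mean_ratio")$w["g", "k"],
               ((0.2 + 0.4) / 2) / 0.8) # 0.375
  expect_equal(compute_weights(probs, "max_ratio")$w["g", "k"], 0.4 / 0.8)
  # zero in-class probability: weight is +Inf for every ratio scheme
  probs$m["g", "k"] <- 0
  expect_identical(compute_weights(probs, "mean_ratio")$w["g", "k"], Inf)
  expect_identical(compute_weights(probs, "max_ratio")$w["g", "k"], Inf)
  # perfectly specific gene: off-class 0, in-class > 0 -> weight 0
  probs$m["g", ] <- c(0.5, 0, 0)
  expect_identical(compute_weights(probs, "mean_ratio")$w["g", "k"], 0)
})

test_that("pooled off-class schemes are cell-weighted", {
  # 3 classes with unequal sizes: pooling cells != averaging class rates
  m <- matrix(c(0.9, 0.1, 0.4), 1, 3,
              dimnames = list("g", c("k", "l1", "l2")))
  probs <- structure(list(m = m, class_sizes = c(k = 5L, l1 = 30L, l2 = 10L)),
                     class = "ClassProbabilities")
  pooled <- (0.1 * 30 + 0.4 * 10) / 40
  expect_equal(compute_weights(probs, "bonferroni")$w["g", "k"], pooled)
  expect_equal(compute_weights(probs, "log_complement")$w["g", "k"],
               -log(1 - pooled))
  # worked example: pooled probability 0.2 -> -log(0.8)
  probs$m["g", c("l1", "l2")] <- 0.2
  expect_equal(compute_weights(probs, "log_complement")$w["g", "k"],
               -log(0.8), tolerance = 1e-12)
})

test_that("candidate_set applies both filters with paper defaults", {
  m <- matrix(c(0.5, 0.05, 0.5,   0.6, 0.015, 0.45), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("k", "l")))
  probs <- structure(list(m = m, class_sizes = c(k = 20L, l = 20L)),
                     class = "ClassProbabilities")
  wt <- compute_weights(probs, "mean_ratio")
  # w(gA,k) = 0.6/0.5 = 1.2 > 1 -> excluded although m = 0.5
  # w(gB,k) = 0.3 but m = 0.05 < 0.1 -> excluded
  # w(gC,k) = 0.9, m = 0.5 -> included
  expect_equal(wt$w[, "k"], c(gA = 1.2, gB = 0.3, gC = 0.9))
  expect_identical(candidate_set(wt, "k"), "gC")
  # candidates always have strictly positive in-class probability
  expect_true(all(probs$m[candidate_set(wt, "k"), "k"] > 0))
})

test_that("ratio weight properties hold on random probability tables", {
  set.seed(101)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    m <- matrix(runif(40 * K), 40, K,
                dimnames = list(sprintf("g%02d", 1:40), paste0("k", 1:K)))
    probs <- structure(list(m = m,
                            class_sizes = stats::setNames(
                              sample(5:30, K, TRUE), colnames(m))),
                       class = "ClassProbabilities")
    wmean <- compute_weights(probs, "mean_ratio")$w
    wmax <- compute_weights(probs, "max_ratio")$w
    expect_true(all(wmean <= wmax + 1e-12))
    if (K == 2) expect_equal(wmean, wmax)
    # invariance under permutation of the non-target classes
    k <- colnames(m)[1]
    perm <- c(k, sample(setdiff(colnames(m), k)))
    probs2 <- probs
    probs2$m <- probs2$m[, perm]
    probs2$class_sizes <- probs2$class_sizes[perm]
    expect_equal(compute_weights(probs2, "mean_ratio")$w[, k], wmean[, k])
    expect_equal(compute_weights(probs2, "max_ratio")$w[, k], wmax[, k])
  }
})

test_that("estimate_mean_lognorm averages log-normalized expression", {
  counts <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"),
                                            c("c1", "c2", "c3")))
  counts["g1", ] <- c(10, 40, 0)
  counts["g2", ] <- c(90, 60, 0) # depths: 100, 100, 0
  m <- expression_matrix(counts, labels = c("k", "k", "l"))
  res <- estimate_mean_lognorm(m, norm_target = 100)
  expect_equal(res$m["g1", "k"], mean(log1p(c(10, 40))))
  # all-zero cell contributes zero; all-zero gene has mean 0 everywhere
  expect_equal(res$m["g1", "l"], 0)
  expect_equal(res$m["g2", "l"], 0)
  # single-cell class equals that cell's log-normalized value
  m2 <- expression_matrix(counts[, 1:2], labels = c("k", "l"))
  res2 <- estimate_mean_lognorm(m2, norm_target = 100)
  expect_equal(res2$m["g2", "l"], log1p(60))
  # 2-cell class with log-normalized values 1.0 and 3.0 averages to 2.0
  # (pad gene fixes each cell's depth at the normalization target)
  g <- c(expm1(1), expm1(3))
  counts3 <- rbind(g = g, pad = 100 - g)
  colnames(counts3) <- c("c1", "c2")
  m3 <- expression_matrix(counts3, labels = c("k", "k"))
  res3 <- estimate_mean_lognorm(m3, norm_target = 100)
  expect_equal(unname(res3$m["g", "k"]), 2.0, tolerance = 1e-12)
})

test_that("weights_to_table flattens gene x class with candidate flags", {
  m <- matrix(c(0.5, 0.05, 0.6, 0.5), 2, 2,
              dimnames = list(c("gA", "gB"), c("k", "l")))
  probs <- structure(list(m = m, class_sizes = c(k = 20L, l = 20L)),
                     class = "ClassProbabilities")
  tab <- weights_to_table(compute_weights(probs, "mean_ratio"))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$candidate,
               tab$w <= 1 & tab$m >= 0.1)
})
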