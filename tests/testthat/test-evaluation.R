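test_that("cv plans are balanced, stratified and deterministic", {
  genes <- sprintf("g%02d", 1:10)
  labs <- rep(c(TRUE, FALSE), 5)
  p1 <- make_cv_plan(genes, labs, n_folds = 5, seed = 3)
  expect_equal(unname(tabulate(p1$assignment, 5)), rep(2L, 5))
  p2 <- make_cv_plan(genes, labs, n_folds = 5, seed = 3)
  expect_identical(p1$assignment, p2$assignment)
  expect_false(identical(
    p1$assignment, make_cv_plan(genes, labs, 5, seed = 4)$assignment))
  expect_error(make_cv_plan(genes, labs, n_folds = 6), "smallest class")
  expect_error(make_cv_plan(c("a", "a", "b"), c(1, 1, 0), 1), "unique")
})

test_that("cv plan stratification holds for uneven classes", {
  set.seed(41)
  for (rep in 1:10) {
    n_pos <- sample(7:20, 1); n_neg <- sample(10:40, 1)
    genes <- sprintf("g%03d", seq_len(n_pos + n_neg))
    labs <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    plan <- make_cv_plan(genes, labs, 5, seed = rep)
    # every fold's positive count within 1 of the expected share
    pos_per_fold <- tapply(labs, plan$assignment[genes], sum)
    expect_true(all(abs(pos_per_fold - n_pos / 5) <= 1))
    sizes <- tabulate(plan$assignment, 5)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("roc_auc reproduces known values and handles ties", {
  expect_equal(roc_auc(c(2, 1), c(1, 0)), 1)
  expect_equal(roc_auc(c(1, 2), c(1, 0)), 0)
  expect_equal(roc_auc(c(3, 2, 2, 1), c(1, 0, 1, 0)), 0.875)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "one class")
})

test_that("roc_auc equals the all-pairs oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))  # rounded: frequent ties
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
  }
})

test_that("roc_auc symmetry and invariance to monotone transforms", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    y <- c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))
    s <- rnorm(n)  # continuous: tie-free almost surely
    expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
    expect_equal(roc_auc(exp(2 * s), y), roc_auc(s, y))
    expect_equal(roc_auc(rank(s), y), roc_auc(s, y))
  }
})

test_that("roc curves run from (0,0) to (1,1) monotonically", {
  set.seed(44)
  s <- round(rnorm(40), 1)
  y <- sample(c(0, 1), 40, replace = TRUE)
  pts <- roc_points(s, y)
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("a separable dataset evaluates to AUC 1 in every fold", {
  ds <- toy_dataset(n_pos = 10, n_neg = 15, sep = 4)
  ev <- evaluate_strategies(ds, "target", config = fast_config())
  for (st in ev$strategies) {
    expect_equal(st$per_fold_auc, rep(1, 5),
                 tolerance = 1e-9, label = st$strategy)
  }
  # EvalResult invariants
  tl <- ev$strategies$two_level
  expect_length(tl$per_fold_auc, 5)
  expect_gte(tl$mean_auc, min(tl$per_fold_auc))
  expect_lte(tl$mean_auc, max(tl$per_fold_auc))
})

test_that("the nested procedure never leaks genes across splits", {
  ds <- toy_dataset(n_pos = 8, n_neg = 12, sep = 2, seed = 9)
  cfg <- image_model_config(grid_C = 1, grid_gamma = c(0.25, 1),
                            gene_grid_C = c(0.1, 1), seed = 2)
  ev <- evaluate_strategies(ds, "target",
                            strategies = c("two_level", "single_image"),
                            config = cfg)
  expect_true(audit_no_leakage(ev))
  # and the audit actually recorded outer + inner splits
  levels <- vapply(ev$audit, `[[`, character(1), "level")
  expect_setequal(unique(levels), c("outer", "inner_grid", "inner_oof"))
})

test_that("evaluation is reproducible and seed-sensitive only in folds", {
  ds <- toy_dataset(n_pos = 8, n_neg = 12, sep = 3, seed = 10)
  e1 <- evaluate_layer(ds, "target", config = fast_config(seed = 5))
  e2 <- evaluate_layer(ds, "target", config = fast_config(seed = 5))
  expect_equal(e1$strategies$two_level$per_fold_auc,
               e2$strategies$two_level$per_fold_auc)
})

test_that("one_vs_one_confusion rejects degenerate class lists", {
  ds <- toy_dataset()
  expect_error(one_vs_one_confusion(ds, layers = "target"), "at least two")
  expect_error(one_vs_one_confusion(ds, layers = c("target", "target")),
               "distinct")
  expect_error(evaluate_strategies(ds, "target", negative_class = "target"),
               "differ")
})

test_that("subset_factors slices the per-level feature blocks", {
  ds <- small_dataset()
  s1 <- subset_factors(ds, 2)
  expect_equal(ncol(s1$features), 257)
  expect_equal(s1$features[, 1:257],
               ds$features[, 257 + 1:257])
  expect_error(subset_factors(ds, 7), "not present")
})

test_that("single-factor ablation equals evaluate_layer at that factor", {
  ds <- small_dataset()
  cfg <- fast_config()
  ab <- resolution_ablation(ds, "granular", factors = 2L, config = cfg)
  ev <- evaluate_layer(subset_factors(ds, 2L), "granular", config = cfg)
  expect_equal(ab$mean_auc[1], ev$strategies$two_level$mean_auc)
  expect_equal(ab$factor, c("2", "multi"))
  # with a single requested factor, "multi" uses the same features
  expect_equal(ab$mean_auc[2], ab$mean_auc[1])
})
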