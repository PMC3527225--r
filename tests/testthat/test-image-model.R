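test_that("separable clusters are scored with the right signs", {
  set.seed(1)
  X <- matrix(c(rnorm(20, 3), rnorm(30, -3)), ncol = 1)
  y <- rep(c(1, 0), c(20, 30))
  m <- train_image_classifier(X, y, image_model_config(cost = 10,
                                                       kernel_width = 0.5))
  s <- score_images(m, X)
  expect_true(all(s[y == 1] > 0))
  expect_true(all(s[y == 0] < 0))
  # scoring is deterministic
  expect_identical(score_images(m, X), s)
  expect_equal(score_image(m, X[1, ]), s[1])
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(train_image_classifier(X, rep(1, 10)), "positive and")
  expect_error(train_image_classifier(X, rep(0, 10)), "positive and")
  expect_error(train_image_classifier(X, rep(c(0, 1), 4)), "disagree")
  m <- train_image_classifier(X, rep(c(0, 1), 5))
  expect_error(score_images(m, matrix(0, 1, 3)), "does not match")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(3)
  n_genes <- 40
  genes <- sprintf("g%02d", seq_len(n_genes))
  gene_y <- rep(c(TRUE, FALSE), n_genes / 2)
  rows <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    cbind(i, matrix(rnorm(3 * 4, mean = ifelse(gene_y[i], 1, -1)),
                    ncol = 4))
  }))
  groups <- genes[rows[, 1]]
  X <- rows[, -1]
  aucs <- replicate(20, {
    y_perm <- gene_y[sample(n_genes)][match(groups, genes)]
    plan <- make_cv_plan(genes, gene_y[sample(n_genes)],
                         n_folds = 5, seed = sample.int(1e6, 1))
    # simple 5-fold CV at fixed hyper-parameters
    oof <- rep(NA_real_, nrow(X))
    for (f in 1:5) {
      te <- plan$assignment[groups] == f
      m <- train_image_classifier(X[!te, ], y_perm[!te],
                                  image_model_config(kernel_width = 0.1))
      oof[te] <- score_images(m, X[te, ])
    }
    roc_auc(oof, y_perm)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("grid search returns the single point of a 1-point grid", {
  set.seed(2)
  X <- matrix(rnorm(40), ncol = 2)
  y <- rep(c(1, 0), 10)
  groups <- paste0("g", seq_len(20))
  gs <- grid_search_hyperparams(X, y, groups,
                                image_model_config(grid_C = 2,
                                                   grid_gamma = 0.25))
  expect_equal(gs$cost, 2)
  expect_equal(gs$kernel_width, 0.25)
  expect_equal(nrow(gs$table), 1)
})

test_that("grid search prefers regularization on a noisy toy set", {
  # one informative dimension + label noise: a huge C with a wide-enough
  # gamma memorizes the noise, small C generalizes
  set.seed(21)
  n <- 80
  y <- rep(c(TRUE, FALSE), n / 2)
  X <- cbind(ifelse(y, 0.5, -0.5) + rnorm(n, sd = 1.2))
  groups <- paste0("g", seq_len(n))
  gs <- grid_search_hyperparams(
    X, y, groups,
    image_model_config(grid_C = c(0.1, 1000), grid_gamma = 2, seed = 2))
  expect_equal(gs$cost, 0.1)
  best_auc <- gs$table$auc[gs$table$C == 0.1]
  expect_gt(best_auc, gs$table$auc[gs$table$C == 1000])
})

test_that("duplicating negatives is equivalent to doubling their cost", {
  set.seed(6)
  X <- matrix(c(rnorm(10, 1.5), rnorm(10, -1.5)), ncol = 1)
  y <- rep(c(TRUE, FALSE), each = 10)
  K <- exp(-0.5 * cereblayers:::sqdist(X))
  dup <- c(seq_len(20), which(!y))
  Kd <- K[dup, dup]
  m1 <- cereblayers:::ksvm_fit(Kd, y[dup], C = 1,
                               class_weights = c(pos = 1, neg = 1))
  m2 <- cereblayers:::ksvm_fit(K, y, C = 1,
                               class_weights = c(pos = 1, neg = 2))
  s1 <- cereblayers:::ksvm_decision(m1, Kd[seq_len(20), , drop = FALSE])
  s2 <- cereblayers:::ksvm_decision(m2, K)
  expect_equal(s1, s2, tolerance = 0.02)
})

test_that("training-set AUC is at least held-out AUC on synthetic data", {
  ds <- small_dataset()
  y <- ds$meta$label == "granular"
  genes <- unique(ds$meta$gene_id)
  gl <- vapply(genes, function(g) y[match(g, ds$meta$gene_id)], logical(1))
  plan <- make_cv_plan(genes, gl, n_folds = 3, seed = 2)
  te <- plan$assignment[ds$meta$gene_id] == 1
  m <- train_image_classifier(ds$features[!te, ], y[!te],
                              image_model_config(cost = 10,
                                                 kernel_width = 8))
  auc_train <- roc_auc(score_images(m, ds$features[!te, ]), y[!te])
  auc_test <- roc_auc(score_images(m, ds$features[te, ]), y[te])
  expect_gte(auc_train, auc_test - 1e-9)
})
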