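# Internal weighted RBF-SVM engine.
#
# The nested cross-validation refits the same data many times over a grid
# of (C, gamma). All fits therefore run on precomputed kernel matrices:
# the squared-distance matrix of a task is computed once (BLAS), each
# gamma's kernel is one exponential away, and every fold/grid-point fit is
# a bare QP on a submatrix. Decision-value orientation in libsvm depends
# on internal label order, so each fit stores an explicit sign determined
# from the training decisions (positives must score higher on average).

# Pairwise squared Euclidean distances; Y = NULL means within X.
sqdist <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  sx <- rowSums(X^2)
  sy <- rowSums(Y^2)
  d <- matrix(sx, nrow(X), nrow(Y)) +
    matrix(sy, nrow(X), nrow(Y), byrow = TRUE) - 2 * tcrossprod(X, Y)
  d[d < 0] <- 0
  d
}

# Inverse-class-frequency misclassification costs: c+ / c- = n- / n+.
class_cost_weights <- function(y) {
  n_pos <- sum(y); n_neg <- sum(!y)
  c(pos = n_neg / n_pos, neg = 1)
}

# Fit a C-SVC on a precomputed kernel matrix. y is logical (positive?).
ksvm_fit <- function(K, y, C, class_weights = class_cost_weights(y)) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                       C = C, class.weights = class_weights)
  svi <- kernlab::SVindex(fit)
  dec <- kernlab::predict(fit,
                          kernlab::as.kernelMatrix(K[, svi, drop = FALSE]),
                          type = "decision")[, 1]
  sgn <- if (mean(dec[y]) >= mean(dec[!y])) 1 else -1
  list(fit = fit, svi = svi, sign = sgn)
}

# Signed decision values for rows of a (test x train) kernel matrix.
ksvm_decision <- function(model, K_cross) {
  dec <- kernlab::predict(
    model$fit,
    kernlab::as.kernelMatrix(K_cross[, model$svi, drop = FALSE]),
    type = "decision")[, 1]
  model$sign * dec
}

# Gene-grouped grid search over (C, gamma) on a precomputed distance
# matrix. Each grid point is scored by the AUC of its out-of-fold decision
# values pooled across the inner folds -- the same way the gene-level
# stage later consumes image scores. Pooling (rather than averaging
# fold-wise AUCs) matters: a degenerate point can rank perfectly within
# every fold while its decision offsets drift between refits, and only
# the pooled AUC exposes that instability. Ties break toward smaller C
# (stronger regularization), then smaller gamma.
# Median-heuristic RBF width: gamma = 1 / median squared distance, so that
# gamma * d^2 is of order 1 for typical pairs. Guards degenerate all-equal
# inputs.
median_gamma <- function(D) {
  m <- stats::median(D[upper.tri(D)])
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}

grid_search_dist <- function(D, y, groups, grid_C, grid_gamma,
                             n_folds = 5, seed = 1) {
  if (is.null(grid_gamma)) {
    # multipliers stay below 2^2: for gamma >> 1/median(d^2) the kernel
    # matrix approaches the identity and SMO convergence degrades badly
    grid_gamma <- median_gamma(D) * 2^seq(-4, 2, by = 2)
  }
  if (length(grid_C) == 1 && length(grid_gamma) == 1) {
    return(list(cost = grid_C, kernel_width = grid_gamma,
                table = data.frame(C = grid_C, gamma = grid_gamma,
                                   auc = NA_real_),
                splits = list()))
  }
  genes <- unique(groups)
  gene_lab <- vapply(genes, function(g) y[match(g, groups)], logical(1))
  # a class smaller than the fold count caps the inner fold count
  n_folds <- min(n_folds, min(table(gene_lab)))
  plan <- make_cv_plan(genes, gene_lab, n_folds = n_folds, seed = seed)
  folds <- lapply(seq_len(n_folds), function(f) {
    te_g <- genes[plan$assignment == f]
    list(test = which(groups %in% te_g),
         train = which(!groups %in% te_g),
         train_genes = setdiff(genes, te_g), test_genes = te_g)
  })
  tab <- expand.grid(C = grid_C, gamma = grid_gamma,
                     KEEP.OUT.ATTRS = FALSE)
  tab$auc <- NA_real_
  for (g in grid_gamma) {
    K <- exp(-g * D)
    for (ci in seq_along(grid_C)) {
      oof <- rep(NA_real_, length(y))
      for (fd in folds) {
        m <- ksvm_fit(K[fd$train, fd$train, drop = FALSE], y[fd$train],
                      grid_C[ci])
        oof[fd$test] <- ksvm_decision(
          m, K[fd$test, fd$train, drop = FALSE])
      }
      tab$auc[tab$C == grid_C[ci] & tab$gamma == g] <- roc_auc(oof, y)
    }
  }
  best <- tab[order(-tab$auc, tab$C, tab$gamma), ][1, ]
  list(cost = best$C, kernel_width = best$gamma, table = tab,
       splits = lapply(folds, function(fd) fd[c("train_genes", "test_genes")]))
}
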