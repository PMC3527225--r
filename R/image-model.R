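#' Configuration for the image-level RBF-SVM classifier
#'
#' @param cost Regularization parameter C used when training without grid
#'   search.
#' @param kernel_width RBF kernel hyper-parameter gamma in
#'   `exp(-gamma * |x - y|^2)`; `NULL` defaults to the median heuristic
#'   (`1 /` median squared distance of the training features).
#' @param grid_C Candidate C values for [grid_search_hyperparams()];
#'   log-spaced over `2^-3 .. 2^7`.
#' @param grid_gamma Candidate gamma values, or `NULL` (default) for the
#'   median heuristic: `1 / median squared distance` of the training
#'   features, times multipliers `2^{-4, -2, 0, 2}`. The adaptive grid
#'   matters because max-scaled LBP histograms are sparse and close
#'   together (typical squared distances far below 1), and it keeps every
#'   candidate kernel away from the near-constant and near-identity
#'   regimes where the SMO solver converges very slowly.
#' @param gene_grid_C Candidate C values for the linear gene-level SVM.
#' @param n_folds Folds for the inner (hyper-parameter) cross-validation.
#' @param k Number of top image scores pooled at the gene level, see
#'   [pool_scores()].
#' @param seed Seed for fold shuffling; scoring itself is deterministic.
#' @return An object of class `image_model_config`.
#' @export
image_model_config <- function(cost = 1, kernel_width = NULL,
                               grid_C = 2^seq(-3, 7, by = 2),
                               grid_gamma = NULL,
                               gene_grid_C = 2^seq(-6, 4, by = 2),
                               n_folds = 5L, k = 3L, seed = 1L) {
  stopifnot(length(grid_C) >= 1, all(grid_C > 0), cost > 0,
            is.null(grid_gamma) ||
              (length(grid_gamma) >= 1 && all(grid_gamma > 0)),
            is.null(kernel_width) || kernel_width > 0, k >= 1)
  structure(list(cost = cost, kernel_width = kernel_width,
                 grid_C = grid_C, grid_gamma = grid_gamma,
                 gene_grid_C = gene_grid_C, n_folds = as.integer(n_folds),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "image_model_config")
}

#' Train the image-level classifier
#'
#' Fits an RBF-kernel support vector machine on image feature vectors.
#' Class imbalance (many more negative than positive images) is handled by
#' weighting misclassification costs inversely to class frequency:
#' `c+ : c- = n- : n+`. The returned model produces a signed decision
#' score per image — the distance from the separating hyperplane, with
#' positive meaning predicted member of the target layer.
#'
#' @param features Numeric matrix, one row per image.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 = target layer.
#' @param config An [image_model_config()]; `cost` and `kernel_width` are
#'   used as-is (run [grid_search_hyperparams()] first to tune them).
#' @return An object of class `image_svm`.
#' @export
train_image_classifier <- function(features, labels,
                                   config = image_model_config()) {
  y <- as_binary(labels)
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(y)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  if (!any(y) || all(y)) {
    stop("training needs at least one positive and one negative image",
         call. = FALSE)
  }
  D <- sqdist(features)
  gamma <- config$kernel_width %||% median_gamma(D)
  K <- exp(-gamma * D)
  m <- ksvm_fit(K, y, config$cost)
  structure(list(X = features, gamma = gamma, cost = config$cost,
                 model = m, n_features = ncol(features)),
            class = "image_svm")
}

#' @export
print.image_svm <- function(x, ...) {
  cat(sprintf("<image_svm> RBF SVM: C = %g, gamma = %g, %d features, %d SVs\n",
              x$cost, x$gamma, x$n_features, length(x$model$svi)))
  invisible(x)
}

#' Score images with a trained image classifier
#'
#' @param model An `image_svm` from [train_image_classifier()].
#' @param features Numeric matrix (or single vector) of feature vectors
#'   with the same length as at training.
#' @return Numeric vector of signed decision scores, one per row.
#' @export
score_images <- function(model, features) {
  if (!inherits(model, "image_svm")) stop("not an image_svm", call. = FALSE)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$n_features) {
    stop("feature length ", ncol(features), " does not match training (",
         model$n_features, ")", call. = FALSE)
  }
  K <- exp(-model$gamma * sqdist(features, model$X))
  ksvm_decision(model$model, K)
}

#' @rdname score_images
#' @export
score_image <- function(model, features) {
  score_images(model, features)[1]
}

#' Gene-grouped grid search for the SVM hyper-parameters
#'
#' Selects `(C, gamma)` maximizing the AUC of out-of-fold decision scores
#' under gene-grouped cross-validation (all images of a gene stay on one
#' side of every split). Scores are pooled across folds before computing
#' the AUC, so grid points whose decision values are unstable between
#' refits are penalized — important because the gene-level classifier is
#' later trained on exactly such pooled out-of-fold scores. Ties break
#' toward smaller C (stronger regularization), then smaller gamma.
#'
#' @inheritParams train_image_classifier
#' @param groups Gene id of each image (same length as `labels`).
#' @return A list with `cost`, `kernel_width`, the full AUC `table`, and
#'   the inner train/test gene `splits`.
#' @export
grid_search_hyperparams <- function(features, labels, groups,
                                    config = image_model_config()) {
  y <- as_binary(labels)
  if (!is.matrix(features)) features <- as.matrix(features)
  stopifnot(nrow(features) == length(y), length(groups) == length(y))
  grid_search_dist(sqdist(features), y, groups,
                   grid_C = config$grid_C, grid_gamma = config$grid_gamma,
                   n_folds = config$n_folds, seed = config$seed)
}
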