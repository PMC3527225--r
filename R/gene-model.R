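#' Pool a gene's image scores into order and moment statistics
#'
#' A gene has a variable number of images (typically 2-8), so its image
#' scores are reduced to a fixed-length summary: the mean, the median and
#' the k-top scores (k = 3 by default, i.e. first, second and third max —
#' 5 features in total). When a gene has fewer than k scores, the lowest
#' available score is duplicated to fill the missing top-k values; the
#' mean and median are computed on the original, unduplicated scores.
#'
#' @param scores Numeric vector of image scores (at least one, all
#'   finite).
#' @param k Number of top statistics.
#' @return Named numeric vector `(mean, median, top1, ..., topk)`.
#' @export
#' @examples
#' pool_scores(c(0.9, 0.5, 0.2))
#' pool_scores(0.4)          # single image: all five equal
#' pool_scores(c(1, 2))      # top-3 filled with the minimum: 2, 1, 1
pool_scores <- function(scores, k = 3L) {
  if (length(scores) < 1) stop("no scores to pool", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  aug <- sort(scores, decreasing = TRUE)
  if (length(aug) < k) {
    aug <- c(aug, rep(min(scores), k - length(aug)))
  }
  c(mean = mean(scores), median = median(scores),
    setNames(aug[seq_len(k)], paste0("top", seq_len(k))))
}

# Pool per-gene: scores + gene ids -> genes x (2 + k) matrix.
pool_by_gene <- function(scores, gene_ids, k = 3L) {
  genes <- unique(gene_ids)
  out <- t(vapply(genes, function(g) pool_scores(scores[gene_ids == g], k),
                  numeric(2 + k)))
  rownames(out) <- genes
  out
}

#' Train the gene-level linear classifier
#'
#' Fits a linear SVM on pooled image-score statistics (one row per gene).
#' The regularization parameter C is tuned by stratified 5-fold
#' cross-validation at the gene level, maximizing AUC; misclassification
#' costs are weighted inversely to class frequency as at the image level.
#'
#' @param pools Numeric matrix of pooled statistics, one row per gene
#'   (e.g. from [pool_scores()]).
#' @param labels Binary gene labels.
#' @param config An [image_model_config()] (supplies `gene_grid_C`,
#'   `n_folds`, `seed`).
#' @return An object of class `gene_svm` with explicit linear weights
#'   `w` and offset `b`; the decision score is `pools %*% w + b`.
#' @export
train_gene_classifier <- function(pools, labels,
                                  config = image_model_config()) {
  y <- as_binary(labels)
  if (!is.matrix(pools)) pools <- as.matrix(pools)
  stopifnot(nrow(pools) == length(y))
  if (!any(y) || all(y)) {
    stop("training needs at least one gene per class", call. = FALSE)
  }
  genes <- rownames(pools) %||% as.character(seq_len(nrow(pools)))
  grid_C <- config$gene_grid_C
  cv_auc <- rep(NA_real_, length(grid_C))
  if (length(grid_C) > 1 && sum(y) >= config$n_folds &&
      sum(!y) >= config$n_folds) {
    plan <- make_cv_plan(genes, y, n_folds = config$n_folds,
                         seed = config$seed)
    cv_auc <- vapply(grid_C, function(C) {
      oof <- rep(NA_real_, length(y))
      for (f in seq_len(config$n_folds)) {
        te <- plan$assignment[genes] == f
        m <- linear_svm_fit(pools[!te, , drop = FALSE], y[!te], C)
        oof[te] <- linear_svm_decision(m, pools[te, , drop = FALSE])
      }
      roc_auc(oof, y)
    }, numeric(1))
    best_C <- grid_C[order(-cv_auc, grid_C)][1]
  } else {
    best_C <- grid_C[1]
  }
  m <- linear_svm_fit(pools, y, best_C)
  structure(list(w = m$w, b = m$b, cost = best_C, cv_auc = cv_auc,
                 feature_names = colnames(pools)),
            class = "gene_svm")
}

# Weighted linear SVM via e1071; extracts explicit (w, b) oriented so that
# positives score higher.
linear_svm_fit <- function(X, y, C) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  wts <- class_cost_weights(y)
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = wts)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  dec <- drop(X %*% w) + b
  if (mean(dec[y]) < mean(dec[!y])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

linear_svm_decision <- function(m, X) {
  drop(X %*% m$w) + m$b
}

#' Score pooled gene statistics with a trained gene classifier
#'
#' @param model A `gene_svm` from [train_gene_classifier()].
#' @param pools Pooled-statistics matrix (or single vector).
#' @return Numeric vector of signed gene-level decision scores.
#' @export
score_gene_pools <- function(model, pools) {
  if (!inherits(model, "gene_svm")) stop("not a gene_svm", call. = FALSE)
  if (is.null(dim(pools))) pools <- matrix(pools, nrow = 1)
  drop(pools %*% model$w) + model$b
}

#' @export
print.gene_svm <- function(x, ...) {
  cat(sprintf("<gene_svm> linear SVM over (%s), C = %g\n",
              paste(x$feature_names, collapse = ", "), x$cost))
  invisible(x)
}

#' Predict the layer membership score of one gene
#'
#' Combines the scores of all (non-blank) images of a gene into a
#' gene-level decision, by one of four strategies:
#' * `two_level`: pool image scores ([pool_scores()]) and apply the
#'   gene-level linear SVM — the full two-level classifier.
#' * `mean_image_score`: arithmetic mean of the image scores.
#' * `mean_lbp_features`: score the per-gene averaged feature vector with
#'   the image model (which should itself be trained on gene-averaged
#'   features).
#' * `single_image`: score each image independently; returns one row per
#'   image (evaluation then treats each image as a sample).
#'
#' @param strategy One of the four strategies above.
#' @param image_model An `image_svm`.
#' @param gene_model A `gene_svm` (required for `two_level`).
#' @param features Feature matrix of the gene's images (one row each).
#' @param gene_id Gene identifier recorded in the output.
#' @return A data frame with columns `gene_id`, `strategy`, `score` (one
#'   row, or one row per image for `single_image`).
#' @export
predict_gene <- function(strategy = c("two_level", "mean_image_score",
                                      "mean_lbp_features", "single_image"),
                         image_model, gene_model = NULL, features,
                         gene_id = "gene") {
  strategy <- match.arg(strategy)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (nrow(features) == 0) {
    stop("gene ", gene_id, " has no non-blank images; unscorable",
         call. = FALSE)
  }
  if (strategy == "mean_lbp_features") {
    score <- score_image(image_model, colMeans(features))
    return(data.frame(gene_id = gene_id, strategy = strategy, score = score))
  }
  s <- score_images(image_model, features)
  if (strategy == "single_image") {
    return(data.frame(gene_id = gene_id, strategy = strategy, score = s))
  }
  score <- switch(strategy,
    two_level = {
      if (is.null(gene_model)) {
        stop("two_level strategy needs a gene_model", call. = FALSE)
      }
      score_gene_pools(gene_model, pool_scores(s))
    },
    mean_image_score = mean(s)
  )
  data.frame(gene_id = gene_id, strategy = strategy, score = score)
}

#' Rank genes by predicted layer membership
#'
#' Scores every gene of an (unlabeled) featurized dataset and sorts by
#' descending score; ties break deterministically by gene id.
#'
#' @param image_model An `image_svm`.
#' @param gene_model A `gene_svm` (needed for `strategy = "two_level"`).
#' @param dataset An `ish_features` object ([featurize_manifest()]).
#' @param strategy A gene-level strategy: `two_level`,
#'   `mean_image_score` or `mean_lbp_features`.
#' @return Data frame `gene_id, strategy, score, rank`, best first.
#' @export
rank_genome <- function(image_model, gene_model = NULL, dataset,
                        strategy = c("two_level", "mean_image_score",
                                     "mean_lbp_features")) {
  strategy <- match.arg(strategy)
  genes <- unique(dataset$meta$gene_id)
  preds <- do.call(rbind, lapply(genes, function(g) {
    rows <- dataset$meta$gene_id == g
    predict_gene(strategy, image_model, gene_model,
                 dataset$features[rows, , drop = FALSE], gene_id = g)
  }))
  preds <- preds[order(-preds$score, preds$gene_id), ]
  preds$rank <- seq_len(nrow(preds))
  rownames(preds) <- NULL
  preds
}
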