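#' Gene-grouped, stratified cross-validation plan
#'
#' Assigns genes (not images) to folds, so that all images of a gene fall
#' on the same side of every split — a gene with images in both train and
#' test would leak near-duplicate slices across the split. Folds are
#' stratified by label and sizes differ by at most one gene, both overall
#' and within each class.
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param labels Label per gene (logical, factor or character).
#' @param n_folds Number of folds.
#' @param seed Seed for the within-class shuffles.
#' @return An object of class `cv_plan` with `assignment`, a named
#'   integer vector mapping gene id to fold.
#' @export
make_cv_plan <- function(gene_ids, labels, n_folds = 5L, seed = 1L) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique", call. = FALSE)
  }
  stopifnot(length(labels) == length(gene_ids))
  class_sizes <- table(labels)
  if (n_folds > min(class_sizes)) {
    stop("n_folds (", n_folds, ") exceeds the smallest class (",
         min(class_sizes), " genes)", call. = FALSE)
  }
  assignment <- with_seed(seed, {
    a <- integer(length(gene_ids))
    names(a) <- gene_ids
    offset <- 0L
    for (lv in sort(unique(as.character(labels)))) {
      idx <- which(as.character(labels) == lv)
      perm <- sample(idx)
      a[gene_ids[perm]] <- ((offset + seq_along(perm) - 1L) %% n_folds) + 1L
      offset <- offset + length(perm)
    }
    a
  })
  structure(list(n_folds = as.integer(n_folds), assignment = assignment,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d genes in %d folds (sizes %s)\n",
              length(x$assignment), x$n_folds,
              paste(tabulate(x$assignment, x$n_folds), collapse = ",")))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outranks a random negative, with half credit for ties,
#' evaluated exactly through midranks. Equals trapezoidal integration of
#' the ROC curve.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (logical or 0/1); both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 2, 1), c(1, 0, 1, 0))  # 0.875
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  stopifnot(length(scores) == length(y))
  if (!any(y) || all(y)) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y); n0 <- length(y) - n1
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame of `(fpr, tpr)` starting at (0, 0), ending at
#'   (1, 1), both coordinates non-decreasing; tied scores collapse to one
#'   point.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary(labels)
  if (!any(y) || all(y)) {
    stop("ROC undefined: only one class present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yo <- y[ord]
  tp <- cumsum(yo); fp <- cumsum(!yo)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(!y)),
             tpr = c(0, tp[keep] / sum(y)))
}

#' Nested cross-validated evaluation of the pooling strategies
#'
#' Runs the full two-level pipeline under outer `n_folds`-fold
#' gene-grouped cross-validation for one layer-vs-negative (or
#' layer-vs-layer) task, evaluating up to four gene-level strategies on
#' exactly the same outer folds:
#' `two_level`, `mean_image_score`, `mean_lbp_features`, `single_image`
#' (see [predict_gene()]).
#'
#' Per outer fold: (1) `(C, gamma)` are tuned by an inner gene-grouped
#' grid search on the training genes only; (2) the image classifier is
#' trained on all training images at the tuned point; (3) the gene-level
#' linear SVM is trained on *out-of-fold* image scores of the training
#' genes (an inner 5-fold pass), so the gene model never sees scores from
#' a model trained on the same images; (4) test-fold genes are scored.
#' AUCs are reported per fold (gene-level, or image-level for
#' `single_image`); ROC curves pool the out-of-fold scores across folds.
#'
#' @param dataset An `ish_features` object (all labeled genes).
#' @param layer Target layer, one of [layer_classes()].
#' @param negative_class Class used as negatives: `"negative"` for the
#'   layer-vs-random task, or another layer for one-vs-one.
#' @param strategies Subset of the four strategy names.
#' @param config An [image_model_config()].
#' @param n_folds Number of outer folds.
#' @return An object of class `layer_eval`: per-strategy fold AUCs, mean
#'   and sample standard deviation, pooled scores and ROC points, the
#'   selected hyper-parameters per fold, and an audit record of every
#'   train/test gene split in the nested procedure.
#' @export
evaluate_strategies <- function(dataset, layer,
                                negative_class = "negative",
                                strategies = c("two_level",
                                               "mean_image_score",
                                               "mean_lbp_features",
                                               "single_image"),
                                config = image_model_config(),
                                n_folds = 5L) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (layer == negative_class) {
    stop("layer and negative_class must differ", call. = FALSE)
  }
  meta <- dataset$meta
  keep <- meta$label %in% c(layer, negative_class)
  if (!any(keep)) stop("dataset contains neither class", call. = FALSE)
  X <- dataset$features[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  y <- meta$label == layer
  if (!any(y) || all(y)) {
    stop("need genes of both classes (", layer, " vs ", negative_class,
         ")", call. = FALSE)
  }
  genes <- unique(meta$gene_id)
  gl <- vapply(genes, function(g) y[match(g, meta$gene_id)], logical(1))
  plan <- make_cv_plan(genes, gl, n_folds = n_folds, seed = config$seed)
  D <- sqdist(X)

  use_mlbp <- "mean_lbp_features" %in% strategies
  if (use_mlbp) {
    Xg <- rowsum(X, meta$gene_id)
    Xg <- Xg / as.vector(table(meta$gene_id)[rownames(Xg)])
    Dg <- sqdist(Xg)
    gene_order <- rownames(Xg)
  }

  audit <- list()
  note_split <- function(level, fold, train_genes, test_genes) {
    audit[[length(audit) + 1]] <<- list(level = level, fold = fold,
                                        train_genes = train_genes,
                                        test_genes = test_genes)
  }
  params <- data.frame(fold = seq_len(n_folds), cost = NA_real_,
                       kernel_width = NA_real_)
  fold_scores <- setNames(vector("list", length(strategies)), strategies)

  for (f in seq_len(n_folds)) {
    te_g <- genes[plan$assignment[genes] == f]
    tr_g <- setdiff(genes, te_g)
    tr <- !(meta$gene_id %in% te_g)
    tr_idx <- which(tr); te_idx <- which(!tr)
    note_split("outer", f, tr_g, te_g)

    gs <- grid_search_dist(D[tr_idx, tr_idx, drop = FALSE], y[tr_idx],
                           meta$gene_id[tr_idx],
                           grid_C = config$grid_C,
                           grid_gamma = config$grid_gamma,
                           n_folds = config$n_folds,
                           seed = config$seed + 1000L * f)
    for (sp in gs$splits) {
      note_split("inner_grid", f, sp$train_genes, sp$test_genes)
    }
    params$cost[f] <- gs$cost
    params$kernel_width[f] <- gs$kernel_width

    K <- exp(-gs$kernel_width * D)
    fit <- ksvm_fit(K[tr_idx, tr_idx, drop = FALSE], y[tr_idx], gs$cost)
    s_te <- ksvm_decision(fit, K[te_idx, tr_idx, drop = FALSE])

    # out-of-fold image scores of training genes, for the gene-level SVM
    oof <- rep(NA_real_, length(tr_idx))
    n_inner <- min(config$n_folds, min(table(gl[tr_g])))
    iplan <- make_cv_plan(tr_g, gl[tr_g], n_folds = n_inner,
                          seed = config$seed + 7000L + f)
    for (fi in seq_len(n_inner)) {
      ite_g <- tr_g[iplan$assignment[tr_g] == fi]
      itr <- !(meta$gene_id[tr_idx] %in% ite_g)
      note_split("inner_oof", f, setdiff(tr_g, ite_g), ite_g)
      mfi <- ksvm_fit(K[tr_idx[itr], tr_idx[itr], drop = FALSE],
                      y[tr_idx][itr], gs$cost)
      oof[!itr] <- ksvm_decision(
        mfi, K[tr_idx[!itr], tr_idx[itr], drop = FALSE])
    }
    pools_tr <- pool_by_gene(oof, meta$gene_id[tr_idx], config$k)
    gm <- train_gene_classifier(pools_tr, gl[rownames(pools_tr)], config)

    for (st in strategies) {
      sc <- switch(st,
        two_level = {
          pools_te <- pool_by_gene(s_te, meta$gene_id[te_idx], config$k)
          data.frame(id = rownames(pools_te),
                     score = score_gene_pools(gm, pools_te),
                     positive = gl[rownames(pools_te)])
        },
        mean_image_score = {
          mg <- tapply(s_te, meta$gene_id[te_idx], mean)
          data.frame(id = names(mg), score = as.vector(mg),
                     positive = gl[names(mg)])
        },
        single_image = data.frame(id = meta$image_id[te_idx],
                                  score = s_te, positive = y[te_idx]),
        mean_lbp_features = {
          itr_g <- match(tr_g, gene_order)
          ite_gi <- match(te_g, gene_order)
          Kg <- exp(-gs$kernel_width * Dg)
          fg <- ksvm_fit(Kg[itr_g, itr_g, drop = FALSE], gl[tr_g], gs$cost)
          data.frame(id = te_g,
                     score = ksvm_decision(
                       fg, Kg[ite_gi, itr_g, drop = FALSE]),
                     positive = gl[te_g])
        })
      sc$fold <- f
      fold_scores[[st]] <- rbind(fold_scores[[st]], sc)
    }
  }

  res <- lapply(strategies, function(st) {
    df <- fold_scores[[st]]
    per_fold <- vapply(seq_len(n_folds), function(f) {
      sub <- df[df$fold == f, ]
      roc_auc(sub$score, sub$positive)
    }, numeric(1))
    list(strategy = st, per_fold_auc = per_fold,
         mean_auc = mean(per_fold),
         auc_std = stats::sd(per_fold),
         scores = df,
         roc = roc_points(df$score, df$positive))
  })
  names(res) <- strategies
  structure(list(layer = layer, negative_class = negative_class,
                 n_folds = as.integer(n_folds), strategies = res,
                 params = params, audit = audit),
            class = "layer_eval")
}

#' Evaluate one layer with one strategy
#'
#' Convenience wrapper around [evaluate_strategies()] for a single
#' strategy.
#'
#' @inheritParams evaluate_strategies
#' @param strategy A single strategy name.
#' @return A `layer_eval` object with one strategy entry.
#' @export
evaluate_layer <- function(dataset, layer, strategy = "two_level",
                           negative_class = "negative",
                           config = image_model_config(), n_folds = 5L) {
  evaluate_strategies(dataset, layer, negative_class = negative_class,
                      strategies = strategy, config = config,
                      n_folds = n_folds)
}

#' @export
print.layer_eval <- function(x, ...) {
  cat(sprintf("<layer_eval> %s vs %s, %d outer folds\n",
              x$layer, x$negative_class, x$n_folds))
  for (st in x$strategies) {
    cat(sprintf("  %-18s AUC = %.3f +/- %.3f\n",
                st$strategy, st$mean_auc, st$auc_std))
  }
  invisible(x)
}

#' Verify that no gene leaks across any recorded split
#'
#' Checks the audit trail of a [evaluate_strategies()] run: in every
#' outer, inner-grid-search and inner-out-of-fold split, the train and
#' test gene sets must be disjoint, and inner splits must stay within
#' their outer training genes.
#'
#' @param eval_result A `layer_eval` object.
#' @return `TRUE` (invisibly); stops on any leak.
#' @export
audit_no_leakage <- function(eval_result) {
  stopifnot(inherits(eval_result, "layer_eval"))
  outer_train <- list()
  for (sp in eval_result$audit) {
    if (length(intersect(sp$train_genes, sp$test_genes)) > 0) {
      stop("leak: gene(s) on both sides of a ", sp$level, " split",
           call. = FALSE)
    }
    if (sp$level == "outer") {
      outer_train[[sp$fold]] <- sp$train_genes
    } else {
      ok <- all(c(sp$train_genes, sp$test_genes) %in%
                  outer_train[[sp$fold]])
      if (!ok) {
        stop("leak: inner split of fold ", sp$fold,
             " uses genes outside the outer training set", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' One-vs-one confusion matrix
#'
#' Trains the two-level classifier for every ordered pair of classes
#' (class i as positives, class j as negatives) and reports the
#' classification error `1 - mean cross-validated AUC`, upper-triangular.
#'
#' @param dataset An `ish_features` object.
#' @param layers Classes to compare (at least two).
#' @param config An [image_model_config()].
#' @param n_folds Outer folds per pair.
#' @return A square matrix of `1 - AUC` values; lower triangle and
#'   diagonal are `NA`.
#' @export
one_vs_one_confusion <- function(dataset, layers = layer_classes(),
                                 config = image_model_config(),
                                 n_folds = 5L) {
  if (length(layers) < 2 || anyDuplicated(layers)) {
    stop("layers must be at least two distinct classes", call. = FALSE)
  }
  m <- matrix(NA_real_, length(layers), length(layers),
              dimnames = list(layers, layers))
  for (i in seq_along(layers)) {
    for (j in seq_along(layers)) {
      if (j <= i) next
      ev <- evaluate_strategies(dataset, layer = layers[i],
                                negative_class = layers[j],
                                strategies = "two_level",
                                config = config, n_folds = n_folds)
      m[i, j] <- 1 - ev$strategies$two_level$mean_auc
    }
  }
  m
}

#' Restrict a featurized dataset to a subset of pyramid factors
#'
#' Slices the per-level 257-column blocks of the feature matrix; no
#' recomputation needed.
#'
#' @param dataset An `ish_features` object.
#' @param factors Factors to keep (must be present in the dataset).
#' @return An `ish_features` object over the selected blocks.
#' @export
subset_factors <- function(dataset, factors) {
  cols <- feature_blocks(dataset, factors)
  structure(list(features = dataset$features[, cols, drop = FALSE],
                 meta = dataset$meta, factors = as.integer(factors),
                 config = dataset$config),
            class = "ish_features")
}

#' Resolution ablation: single scales vs the multi-scale representation
#'
#' Evaluates the two-level classifier for one layer using each single
#' downsampling factor alone, then using the concatenated multi-scale
#' representation, on identical folds. Coarse factors capture the folded
#' band geometry; fine factors capture per-layer texture; the multi-scale
#' representation concatenates all of them.
#'
#' @param dataset An `ish_features` object (multi-factor features).
#' @param layer Target layer.
#' @param factors Factors to ablate over (default: all in the dataset).
#' @param config An [image_model_config()].
#' @param negative_class Negative class for the task.
#' @param n_folds Outer folds.
#' @return Data frame with columns `factor` (each single factor, then
#'   `"multi"`), `mean_auc`, `auc_std`.
#' @export
resolution_ablation <- function(dataset, layer,
                                factors = dataset$factors,
                                config = image_model_config(),
                                negative_class = "negative",
                                n_folds = 5L) {
  run1 <- function(sub) {
    ev <- evaluate_strategies(sub, layer, negative_class = negative_class,
                              strategies = "two_level", config = config,
                              n_folds = n_folds)
    c(ev$strategies$two_level$mean_auc, ev$strategies$two_level$auc_std)
  }
  rows <- lapply(factors, function(f) {
    c(f, run1(subset_factors(dataset, f)))
  })
  multi <- run1(subset_factors(dataset, factors))
  out <- data.frame(
    factor = c(as.character(factors), "multi"),
    mean_auc = c(vapply(rows, `[`, numeric(1), 2), multi[1]),
    auc_std = c(vapply(rows, `[`, numeric(1), 3), multi[2])
  )
  out
}
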