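# The classifier: a shallow gradient-boosted tree ensemble (logistic
# objective, depth 3) with positive-class instances weighted 10x, trained on
# the P/N gold set over the 14 features. Missing feature values are routed
# natively by the tree learner, never imputed.

#' Model hyperparameters
#'
#' @param max_depth tree depth (default 3; shallow trees resist overfitting
#'   on collinear features).
#' @param positive_weight instance weight of positive pairs in the logistic
#'   objective (default 10, i.e. positive misclassification penalized 10x).
#' @param n_folds cross-validation folds (default 5).
#' @param n_repeats independent CV repeats ("ensembles", default 100).
#' @param n_trees boosting rounds (default 100).
#' @param learning_rate shrinkage eta (default 0.1).
#' @param seed integer root seed; repeat r of CV uses `seed + r`.
#' @return list of class `fugue_params`.
#' @export
fugue_params <- function(max_depth = 3, positive_weight = 10, n_folds = 5,
                         n_repeats = 100, n_trees = 100, learning_rate = 0.1,
                         seed = 1L) {
  stopifnot(max_depth >= 1, positive_weight > 0, n_folds >= 2,
            n_trees >= 1, learning_rate > 0)
  structure(list(max_depth = as.integer(max_depth),
                 positive_weight = positive_weight,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "fugue_params")
}

.feature_matrix <- function(features) {
  miss <- setdiff(feature_names(), names(features))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(features[, feature_names()])
  storage.mode(m) <- "double"
  m
}

.labeled <- function(features) features[features$label %in% c("P", "N"), ,
                                        drop = FALSE]

#' Train the boosted-tree classifier on labeled pairs
#'
#' @param features data.frame with `gene`, `tissue`, `label` and the 14
#'   [feature_names()] columns; only rows labeled "P"/"N" are used.
#' @param params a [fugue_params()].
#' @return object of class `fugue_model` (fitted booster + metadata).
#' @export
fugue_train <- function(features, params = fugue_params()) {
  lab <- .labeled(features)
  y <- as.integer(lab$label == "P")
  if (length(unique(y)) < 2)
    stop("training needs both a positive and a negative class")
  X <- .feature_matrix(lab)
  w <- ifelse(y == 1, params$positive_weight, 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w, missing = NA)
  set.seed(params$seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth,
                  eta = params$learning_rate,
                  nthread = 1,
                  seed = params$seed),
    data = dtrain, nrounds = params$n_trees, verbose = 0)
  structure(list(booster = booster, params = params,
                 feature_names = feature_names(),
                 n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "fugue_model")
}

#' @export
print.fugue_model <- function(x, ...) {
  cat(sprintf("fugue_model: %d trees, depth %d, trained on %d P / %d N pairs\n",
              x$params$n_trees, x$params$max_depth, x$n_pos, x$n_neg))
  invisible(x)
}

#' Predict pair scores (probabilities) from a fitted model
#' @param object a `fugue_model`.
#' @param newdata data.frame carrying the 14 feature columns.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.fugue_model <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata)
  dm <- xgboost::xgb.DMatrix(X, missing = NA)
  as.numeric(predict(object$booster, dm))
}

#' Within-tissue normalized ranks of scores
#'
#' normalized_rank = rank(score, ties = average) / n per tissue, so ranks
#' lie in (0, 1] with 1 = best.
#'
#' @param score_table data.frame with `tissue` and `score` columns.
#' @return the table with a `normalized_rank` column added/replaced.
#' @export
add_normalized_ranks <- function(score_table) {
  nr <- stats::ave(score_table$score, score_table$tissue,
                   FUN = function(s) rank(s, ties.method = "average") / length(s))
  score_table$normalized_rank <- nr
  score_table
}

.stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("a class has fewer members than the number of folds")
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation
#'
#' Runs `n_repeats` independent rounds of stratified `n_folds`-fold CV;
#' each round pools the held-out predictions over its folds and reports one
#' auROC and auPRC. Repeat r derives its fold assignment and model seed
#' from `params$seed + r`.
#'
#' @param features labeled feature table (only P/N rows used).
#' @param params a [fugue_params()].
#' @param n_repeats override of `params$n_repeats` (handy at desk scale).
#' @return list with `per_repeat` (data.frame repeat, auROC, auPRC),
#'   `auROC_mean`, `auROC_sd`, `auPRC_mean`, `auPRC_sd`.
#' @export
repeated_cv <- function(features, params = fugue_params(),
                        n_repeats = params$n_repeats) {
  lab <- .labeled(features)
  y <- as.integer(lab$label == "P")
  if (length(unique(y)) < 2) stop("both classes required")
  res <- lapply(seq_len(n_repeats), function(r) {
    rseed <- params$seed + r
    fold <- .stratified_folds(y, params$n_folds, rseed)
    pred <- numeric(length(y))
    for (k in seq_len(params$n_folds)) {
      tr <- lab[fold != k, , drop = FALSE]
      p_k <- fugue_params(max_depth = params$max_depth,
                          positive_weight = params$positive_weight,
                          n_folds = params$n_folds, n_repeats = 1,
                          n_trees = params$n_trees,
                          learning_rate = params$learning_rate,
                          seed = rseed)
      fit <- fugue_train(tr, p_k)
      pred[fold == k] <- predict(fit, lab[fold == k, , drop = FALSE])
    }
    m <- auroc_auprc(pred, y)
    data.frame(rep = r, auROC = m[["auROC"]], auPRC = m[["auPRC"]])
  })
  per <- do.call(rbind, res)
  list(per_repeat = per,
       auROC_mean = mean(per$auROC), auROC_sd = sd(per$auROC),
       auPRC_mean = mean(per$auPRC), auPRC_sd = sd(per$auPRC))
}

#' Leave-one-group-out scores for every pair
#'
#' Each labeled pair is scored by a model trained with *all* labeled rows of
#' that pair's gene (by default) held out, preventing leakage across tissues
#' of the same gene. Unlabeled pairs are scored by the model fitted on the
#' full labeled set. Normalized ranks are computed within each tissue over
#' all scored pairs.
#'
#' @param features feature table with labels for all pairs to score.
#' @param params a [fugue_params()].
#' @param group_by `"gene"` (default): the held-out unit.
#' @return score table: gene, tissue, label, score, normalized_rank.
#' @export
loo_pair_scores <- function(features, params = fugue_params(),
                            group_by = "gene") {
  stopifnot(group_by %in% c("gene"))
  features <- as.data.frame(features)
  score <- rep(NA_real_, nrow(features))
  labeled <- features$label %in% c("P", "N")

  full <- fugue_train(features, params)
  score[!labeled] <- if (any(!labeled))
    predict(full, features[!labeled, , drop = FALSE]) else numeric(0)

  for (g in unique(features$gene[labeled])) {
    test_idx <- which(labeled & features$gene == g)
    train <- features[labeled & features$gene != g, , drop = FALSE]
    fit <- fugue_train(train, params)
    score[test_idx] <- predict(fit, features[test_idx, , drop = FALSE])
  }
  out <- data.frame(gene = features$gene, tissue = features$tissue,
                    label = features$label, score = score,
                    stringsAsFactors = FALSE)
  add_normalized_ranks(out)
}

#' Score a held-out tissue with a model never shown that tissue
#'
#' Trains on the labeled pairs of every other tissue and scores all pairs
#' (labeled or not) of the held-out tissue; ranks are within-tissue.
#'
#' @param features feature table covering all tissues.
#' @param params a [fugue_params()].
#' @param tissue the tissue to hold out and score.
#' @return score table for the held-out tissue.
#' @export
leave_one_tissue_out <- function(features, params = fugue_params(), tissue) {
  train <- features[features$tissue != tissue & features$label %in% c("P", "N"), ,
                    drop = FALSE]
  if (nrow(train) == 0) stop("no trainable rows outside tissue ", tissue)
  test <- features[features$tissue == tissue, , drop = FALSE]
  if (nrow(test) == 0) stop("unknown tissue: ", tissue)
  fit <- fugue_train(train, params)
  out <- data.frame(gene = test$gene, tissue = test$tissue,
                    label = test$label, score = predict(fit, test),
                    stringsAsFactors = FALSE)
  add_normalized_ranks(out)
}

#' Split-count (F score) feature importances
#'
#' Number of times each feature is used as a split across the ensemble;
#' features never used report 0, so all 14 are always present.
#'
#' @param model a fitted `fugue_model`.
#' @return named numeric vector over [feature_names()].
#' @export
feature_importances <- function(model) {
  trees <- xgboost::xgb.model.dt.tree(model = model$booster)
  splits <- trees$Feature[trees$Feature != "Leaf"]
  counts <- table(factor(splits, levels = model$feature_names))
  out <- as.numeric(counts)
  names(out) <- model$feature_names
  out
}
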