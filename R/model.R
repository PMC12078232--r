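#' Stratified train/validation split
#'
#' Splits indices into disjoint, exhaustive train and validation sets,
#' stratified by the class label so per-class proportions are preserved
#' within rounding; reproducible by seed.
#'
#' @param y 0/1 labels (each class needs >= 2 members).
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
#' @examples
#' sp <- split_train_validation(rep(c(0, 1), c(86, 94)), 0.8, seed = 7)
#' lengths(sp) # 144 and 36
split_train_validation <- function(y, fraction = 0.8, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    ctv_stop("ctv_split_error", "fraction must be in (0, 1)")
  }
  y <- as.integer(y)
  tab <- table(y)
  if (length(tab) < 2 || any(tab < 2)) {
    ctv_stop("ctv_split_error",
             "each class needs at least 2 members to split")
  }
  with_seed(seed, {
    train <- integer()
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      n_tr <- round(length(idx) * fraction)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, idx[seq_len(n_tr)])
    }
    train <- sort(train)
    list(train = train, validation = setdiff(seq_along(y), train))
  })
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form (midranks for ties), equivalent to trapezoidal
#' integration of the empirical ROC curve and invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric predicted scores.
#' @param y 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    ctv_stop("ctv_metric_error", "AUC undefined: y must contain both classes")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the bagged decision-tree recurrence classifier
#'
#' A random-forest-style ensemble of B decision trees, each grown on a
#' bootstrap resample with random feature subsetting at splits. Predicted
#' probability is the average of the per-tree class probabilities
#' `RF(x) = (1/B) sum_i T_i(x)`; predicted class labels come from the
#' majority vote of the trees. Tree depth and the number of estimators are
#' chosen by grid search maximizing stratified cross-validated AUC (ties
#' resolved by grid order: shallower, smaller ensembles first).
#'
#' @param X numeric feature matrix with named columns (training rows only).
#' @param y 0/1 labels (both classes required).
#' @param depth_grid tree depth candidates; `Inf` (or 0) = unbounded.
#' @param trees_grid ensemble size candidates.
#' @param folds stratified CV folds for the grid search (default 5).
#' @param seed integer seed governing folds, bootstraps and feature
#'   subsetting.
#' @return An object of class `bagged_trees`: list with the fitted `ranger`
#'   ensemble (`fit`), `best` hyperparameters, the full `cv_table`, and the
#'   training feature names.
#' @export
train_model <- function(X, y, depth_grid = c(3, 5, 7, Inf),
                        trees_grid = c(100, 200, 500),
                        folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    ctv_stop("ctv_model_error", "y must contain both classes")
  }
  stopifnot(!is.null(colnames(X)))
  grid <- expand.grid(depth = depth_grid, trees = trees_grid,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    cv_auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      d <- grid$depth[g]
      fold_auc <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- ranger::ranger(
          x = X[tr, , drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
          num.trees = grid$trees[g],
          max.depth = if (is.finite(d)) d else 0,
          probability = TRUE, seed = seed + 7907L * g + f,
          num.threads = 1L, oob.error = FALSE, verbose = FALSE)
        pr <- predict(fit, data = X[!tr, , drop = FALSE],
                      num.threads = 1L)$predictions[, "1"]
        fold_auc[f] <- auc_rank(pr, y[!tr])
      }
      cv_auc[g] <- mean(fold_auc)
    }
    best_g <- which.max(cv_auc) # ties: first in grid order
    d <- grid$depth[best_g]
    final <- ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)),
      num.trees = grid$trees[best_g],
      max.depth = if (is.finite(d)) d else 0,
      probability = TRUE, importance = "impurity",
      seed = seed + 99991L, num.threads = 1L, verbose = FALSE)
    structure(list(
      fit = final,
      best = list(depth = d, num_trees = grid$trees[best_g]),
      cv_table = cbind(grid, cv_auc = cv_auc),
      features = colnames(X),
      seed = seed
    ), class = "bagged_trees")
  })
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat(sprintf("<bagged_trees: %d trees, depth %s, %d features, CV AUC %.3f>\n",
              x$best$num_trees,
              if (is.finite(x$best$depth)) x$best$depth else "unbounded",
              length(x$features),
              max(x$cv_table$cv_auc)))
  invisible(x)
}

#' Predict from a bagged-tree model
#'
#' @param object a `bagged_trees` model.
#' @param newdata matrix/data frame containing the model's feature columns.
#' @param type `"prob"` for the tree-averaged probability of class 1,
#'   `"class"` for the majority vote of the trees.
#' @param ... unused.
#' @return numeric vector of probabilities, or integer 0/1 votes.
#' @export
predict.bagged_trees <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (type == "prob") {
    predict(object$fit, data = newdata,
            num.threads = 1L)$predictions[, "1"]
  } else {
    # per-tree class probabilities -> per-tree vote -> majority
    all_pred <- predict(object$fit, data = newdata, predict.all = TRUE,
                        num.threads = 1L)$predictions
    votes <- apply(all_pred[, 2, , drop = FALSE] > 0.5, 1, mean)
    as.integer(votes > 0.5)
  }
}

#' Classification metrics and ROC curve
#'
#' Accuracy, precision, recall and F1 at the 0.5 probability threshold,
#' AUC by the rank statistic, and the ROC curve over all unique score
#' thresholds. Precision is `NA` when no sample is predicted positive.
#'
#' @param model a `bagged_trees` model (or `NULL` when `scores` given).
#' @param X feature matrix (ignored when `scores` given).
#' @param y 0/1 labels (both classes required).
#' @param scores optional precomputed scores overriding model predictions.
#' @return list of class `model_metrics`: `metrics` (named vector:
#'   accuracy, auc, precision, recall, f1) and `roc` (data frame
#'   `threshold`, `fpr`, `tpr`).
#' @export
evaluate <- function(model, X, y, scores = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    ctv_stop("ctv_metric_error", "AUC undefined: y must contain both classes")
  }
  if (is.null(scores)) scores <- predict(model, X, type = "prob")
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / sum(y == 1)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list_out <- list(
    metrics = c(accuracy = mean(pred == y),
                auc = auc_rank(scores, y),
                precision = precision, recall = recall, f1 = f1),
    roc = roc_points(scores, y))
  class(list_out) <- "model_metrics"
  list_out
}

#' @rdname evaluate
#' @export
roc_points <- function(scores, y) {
  y <- as.integer(y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' @export
print.model_metrics <- function(x, ...) {
  print(round(x$metrics, 4))
  invisible(x)
}
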