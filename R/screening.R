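#' Standardize a feature matrix
#'
#' Centres each column and scales by its *population* standard deviation
#' (denominator n, not n-1), so a 3-point column (1, 2, 3) maps to
#' (-1.2247, 0, 1.2247). Constant columns map to all zeros and are flagged.
#' The fitted transform is stored so it can be applied unchanged to
#' validation rows — standardization parameters must come from training
#' rows only.
#'
#' @param X numeric matrix or data frame of features (n >= 2 rows).
#' @return An object of class `standardizer`: list with `center`, `scale`
#'   (population sd, 1 for constant columns), `constant` (logical flag per
#'   column) and `Z`, the standardized training matrix.
#' @seealso [apply_standardizer()]
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, is.numeric(X))
  center <- colMeans(X)
  dev <- sweep(X, 2, center)
  scale <- sqrt(colMeans(dev^2))
  constant <- scale == 0
  scale[constant] <- 1
  Z <- sweep(dev, 2, scale, `/`)
  Z[, constant] <- 0
  structure(list(center = center, scale = scale, constant = constant, Z = Z),
            class = "standardizer")
}

#' @rdname standardize
#' @param sz a fitted `standardizer`.
#' @param newX matrix with the same columns as the training matrix.
#' @export
apply_standardizer <- function(sz, newX) {
  stopifnot(inherits(sz, "standardizer"))
  newX <- as.matrix(newX)
  stopifnot(ncol(newX) == length(sz$center))
  Z <- sweep(sweep(newX, 2, sz$center), 2, sz$scale, `/`)
  Z[, sz$constant] <- 0
  Z
}

#' Correlation-based redundancy filter
#'
#' Scans feature pairs in schema (column) order; whenever a still-retained
#' pair has `|Pearson r| >= threshold`, the member with the weaker absolute
#' point-biserial correlation to the class label is dropped (ties keep the
#' earlier column). The procedure is deterministic given the column order.
#' Constant columns have undefined correlations and are never dropped here
#' (they carry no redundancy and are neutralized by standardization).
#'
#' @param X numeric feature matrix (columns named).
#' @param y 0/1 class labels.
#' @param threshold pairwise |r| at or above which a pair is redundant,
#'   in (0, 1]; default 0.95.
#' @return list with `kept` (retained column names in original order) and
#'   `dropped` (data frame `kept`, `dropped`, `abs_r` per removal).
#' @export
correlation_filter <- function(X, y, threshold = 0.95) {
  X <- as.matrix(X)
  if (!(threshold > 0 && threshold <= 1)) {
    ctv_stop("ctv_screening_error", "threshold must be in (0, 1]")
  }
  y <- as.numeric(y)
  p <- ncol(X)
  cn <- colnames(X) %||% paste0("V", seq_len(p))
  sds <- apply(X, 2, sd)
  cormat <- suppressWarnings(cor(X))
  label_cor <- suppressWarnings(abs(cor(X, y)))
  label_cor[is.na(label_cor)] <- 0
  keep <- rep(TRUE, p)
  drops <- list()
  for (i in seq_len(p - 1)) {
    if (!keep[i] || sds[i] == 0) next
    for (j in (i + 1):p) {
      if (!keep[j] || sds[j] == 0) next
      r <- cormat[i, j]
      if (!is.na(r) && abs(r) >= threshold) {
        # drop the weaker label correlate; ties keep the earlier column
        victim <- if (label_cor[j] > label_cor[i]) i else j
        survivor <- if (victim == i) j else i
        keep[victim] <- FALSE
        drops[[length(drops) + 1L]] <- data.frame(
          kept = cn[survivor], dropped = cn[victim], abs_r = abs(r),
          stringsAsFactors = FALSE)
        if (victim == i) break
      }
    }
  }
  dropped <- if (length(drops)) do.call(rbind, drops) else
    data.frame(kept = character(), dropped = character(), abs_r = numeric(),
               stringsAsFactors = FALSE)
  list(kept = cn[keep], dropped = dropped)
}

# stratified fold assignment: both classes spread as evenly as possible
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# internal ensemble used to rank features inside the elimination loop:
# moderately sized, depth-limited bagged trees (importance estimates are
# averaged over folds, so modest per-fit resolution suffices)
rfe_fit <- function(X, y, seed, num_trees = 50L, max_depth = 7L) {
  ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                 num.trees = num_trees, max.depth = max_depth,
                 probability = TRUE, importance = "impurity",
                 seed = seed, num.threads = 1L, oob.error = FALSE,
                 verbose = FALSE)
}

#' Recursive feature elimination with stratified cross-validation
#'
#' Starting from all columns, repeatedly: fit the bagged-tree ensemble on
#' each of `folds` stratified training splits, record the mean held-out
#' AUC at the current subset size, average the impurity importances over
#' folds, and remove the `step` lowest-ranked feature(s). The selected
#' subset is the visited size with the highest mean CV AUC; ties go to the
#' smaller subset. A fixed `seed` makes the whole path reproducible.
#'
#' @param X numeric feature matrix with named columns.
#' @param y 0/1 labels (both classes required).
#' @param folds number of stratified CV folds (>= 2; default 5).
#' @param step features removed per iteration (default 1).
#' @param seed integer seed.
#' @param num_trees,max_depth size of the internal ranking ensemble.
#' @return list of class `screening_result`: `selected` (retained feature
#'   names, in elimination-resistance order), `rfe_path` (data frame
#'   `n_features`, `cv_auc`), `best_size`, and `ranking` (all features in
#'   elimination order, last-eliminated first).
#' @export
rfe_cv <- function(X, y, folds = 5L, step = 1L, seed = 1L,
                   num_trees = 50L, max_depth = 7L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    ctv_stop("ctv_screening_error", "y must contain both classes")
  }
  stopifnot(folds >= 2, step >= 1, !is.null(colnames(X)))
  with_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    current <- colnames(X)
    path_sizes <- integer(); path_auc <- numeric()
    elim_order <- character()
    best_auc <- -Inf; best_set <- current
    iter <- 0L
    while (length(current) >= 1L) {
      iter <- iter + 1L
      fold_auc <- numeric(folds)
      imp <- numeric(length(current))
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- rfe_fit(X[tr, current, drop = FALSE], y[tr],
                       seed = seed + 1000L * iter + f,
                       num_trees = num_trees, max_depth = max_depth)
        pr <- predict(fit, data = X[!tr, current, drop = FALSE],
                      num.threads = 1L)$predictions[, "1"]
        fold_auc[f] <- auc_rank(pr, y[!tr])
        imp <- imp + fit$variable.importance[current]
      }
      m_auc <- mean(fold_auc)
      path_sizes <- c(path_sizes, length(current))
      path_auc <- c(path_auc, m_auc)
      # ties -> smaller subset: strict improvement required while shrinking
      if (m_auc >= best_auc) {
        best_auc <- m_auc
        best_set <- current
      }
      if (length(current) == 1L) {
        elim_order <- c(current, elim_order)
        break
      }
      k <- min(step, length(current) - 1L)
      worst <- current[order(imp)][seq_len(k)]
      elim_order <- c(worst, elim_order)
      current <- setdiff(current, worst)
    }
    structure(list(
      selected = best_set,
      rfe_path = data.frame(n_features = path_sizes, cv_auc = path_auc),
      best_size = length(best_set),
      ranking = elim_order
    ), class = "screening_result")
  })
}
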