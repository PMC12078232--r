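#' Fit the full screened recurrence-prediction pipeline
#'
#' One leakage-safe pass over a cohort feature table: stratified 80/20
#' split, standardization fitted on training rows, correlation-based
#' redundancy removal, optional recursive feature elimination with
#' stratified CV, grid-searched bagged-tree training, and evaluation on
#' both subsets. Validation rows influence nothing that is fitted: the
#' standardizer, the filter, the RFE selection and the grid search all see
#' training rows only, and the stored transform is merely applied to the
#' validation rows.
#'
#' @param features data frame with the 110 feature columns (plus optional
#'   `id`) — or any numeric feature columns.
#' @param y 0/1 relapse labels.
#' @param fraction training fraction (default 0.8).
#' @param seed master seed; stage seeds are derived substreams.
#' @param corr_threshold redundancy threshold for [correlation_filter()].
#' @param rfe run [rfe_cv()]? (`TRUE` by default; turn off to isolate the
#'   classifier).
#' @param folds CV folds for both RFE and the grid search.
#' @param step RFE elimination step.
#' @param depth_grid,trees_grid hyperparameter grid for [train_model()].
#' @param split optional precomputed split (list with `train` and
#'   `validation` index vectors) overriding the internal stratified split.
#' @return list of class `recurrence_model_report`: `screening`
#'   (dropped pairs, RFE path, selected features), `model` (best
#'   hyperparameters), `metrics_train`, `metrics_validation`, `roc`
#'   (validation ROC points), `split` sizes, and the fitted `bagged_trees`
#'   in `fit`.
#' @export
fit_recurrence_pipeline <- function(features, y, fraction = 0.8, seed = 1L,
                                    corr_threshold = 0.95, rfe = TRUE,
                                    folds = 5L, step = 1L,
                                    depth_grid = c(3, 5, 7, Inf),
                                    trees_grid = c(100, 200, 500),
                                    split = NULL) {
  X <- as.matrix(features[, setdiff(colnames(features), c("id", "relapse")),
                          drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))

  sp <- split %||%
    split_train_validation(y, fraction, seed = substream_seed(seed, "split"))
  sz <- standardize(X[sp$train, , drop = FALSE])
  Ztr <- sz$Z
  Zva <- apply_standardizer(sz, X[sp$validation, , drop = FALSE])
  colnames(Ztr) <- colnames(Zva) <- colnames(X)

  filt <- correlation_filter(Ztr, y[sp$train], threshold = corr_threshold)
  kept <- filt$kept

  screening <- list(dropped_correlated = filt$dropped, rfe_path = NULL,
                    selected = kept)
  if (rfe) {
    scr <- rfe_cv(Ztr[, kept, drop = FALSE], y[sp$train], folds = folds,
                  step = step, seed = substream_seed(seed, "rfe"))
    screening$rfe_path <- scr$rfe_path
    screening$selected <- scr$selected
  }
  sel <- screening$selected

  model <- train_model(Ztr[, sel, drop = FALSE], y[sp$train],
                       depth_grid = depth_grid, trees_grid = trees_grid,
                       folds = folds, seed = substream_seed(seed, "model"))
  ev_tr <- evaluate(model, Ztr[, sel, drop = FALSE], y[sp$train])
  ev_va <- evaluate(model, Zva[, sel, drop = FALSE], y[sp$validation])

  structure(list(
    screening = screening,
    model = model$best,
    cv_table = model$cv_table,
    metrics_train = ev_tr$metrics,
    metrics_validation = ev_va$metrics,
    roc = ev_va$roc,
    split = list(n_train = length(sp$train), n_validation = length(sp$validation),
                 train = sp$train, validation = sp$validation),
    standardizer = sz[c("center", "scale", "constant")],
    fit = model,
    seed = seed
  ), class = "recurrence_model_report")
}

#' @export
print.recurrence_model_report <- function(x, ...) {
  cat(sprintf(
    "<recurrence_model_report: %d -> %d features, depth %s, %d trees>\n",
    length(x$standardizer$center), length(x$screening$selected),
    if (is.finite(x$model$depth)) x$model$depth else "unbounded",
    x$model$num_trees))
  cat("training:  "); print(round(x$metrics_train, 3))
  cat("validation:"); print(round(x$metrics_validation, 3))
  invisible(x)
}
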