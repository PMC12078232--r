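#' Configuration of a full pipeline run
#'
#' One configuration object drives [run_all()]; every random stage derives
#' its seed from `master_seed`, so a run is fully reproducible from the
#' config alone. Serializes to/from a single YAML file, and the resolved
#' config is archived next to the outputs of every run.
#'
#' @param master_seed integer master seed.
#' @param n cohort size.
#' @param grid_shape,grid_spacing phantom grid geometry.
#' @param gross_disease `"union"` or `"primary_only"` (feature extraction).
#' @param min_overlap_voxels station-involvement threshold (voxels).
#' @param corr_threshold correlation-filter threshold in (0, 1].
#' @param folds CV folds; `rfe_step` RFE elimination step; `rfe` run RFE?
#' @param rfe,rfe_step see `folds`.
#' @param depth_grid,trees_grid hyperparameter grid.
#' @param train_fraction training fraction of the split.
#' @param horizon_months local-control horizon.
#' @param group_covariate,group_cut survival grouping: record covariate and
#'   numeric threshold (default: tumor diameter at 5 cm).
#' @param effect an [effect_spec()] (stored resolved).
#' @return list of class `run_config`.
#' @export
run_config <- function(master_seed = 17L, n = 180L,
                       grid_shape = c(96L, 96L, 96L),
                       grid_spacing = c(1.5, 1.5, 1.5),
                       gross_disease = "union", min_overlap_voxels = 1L,
                       corr_threshold = 0.95, folds = 5L,
                       rfe = TRUE, rfe_step = 1L,
                       depth_grid = c(3, 5, 7, Inf),
                       trees_grid = c(100, 200, 500),
                       train_fraction = 0.8, horizon_months = 36,
                       group_covariate = "tumor_diameter_cm", group_cut = 5,
                       effect = effect_spec()) {
  cfg <- list(master_seed = as.integer(master_seed), n = as.integer(n),
              grid_shape = as.integer(grid_shape),
              grid_spacing = as.numeric(grid_spacing),
              gross_disease = gross_disease,
              min_overlap_voxels = as.integer(min_overlap_voxels),
              corr_threshold = corr_threshold, folds = as.integer(folds),
              rfe = isTRUE(rfe), rfe_step = as.integer(rfe_step),
              depth_grid = depth_grid, trees_grid = trees_grid,
              train_fraction = train_fraction,
              horizon_months = horizon_months,
              group_covariate = group_covariate, group_cut = group_cut,
              effect = effect)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (!(cfg$corr_threshold > 0 && cfg$corr_threshold <= 1)) {
    ctv_stop("ctv_config_error",
             "corr_threshold must be in (0, 1], got %g", cfg$corr_threshold)
  }
  if (!(cfg$train_fraction > 0 && cfg$train_fraction < 1)) {
    ctv_stop("ctv_config_error", "train_fraction must be in (0, 1)")
  }
  if (cfg$n < 2) ctv_stop("ctv_config_error", "n must be >= 2")
  if (!cfg$gross_disease %in% c("union", "primary_only")) {
    ctv_stop("ctv_config_error", "gross_disease must be union or primary_only")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$effect <- unclass(x$effect)
  x$effect$involved_station_probs <- as.list(x$effect$involved_station_probs)
  x$effect$logit_coefficients <- as.list(x$effect$logit_coefficients)
  x$effect$hazard_ratio_per_unit <- as.list(x$effect$hazard_ratio_per_unit)
  x$effect$recurrence_station_weights <- as.list(x$effect$recurrence_station_weights)
  x$depth_grid <- ifelse(is.finite(x$depth_grid), x$depth_grid, -1) # -1 = unbounded
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  eff <- x$effect
  effect <- effect_spec(
    involved_station_probs = unlist(eff$involved_station_probs),
    logit_intercept = eff$logit_intercept,
    logit_coefficients = unlist(eff$logit_coefficients),
    baseline_hazard = eff$baseline_hazard,
    hazard_ratio_per_unit = unlist(eff$hazard_ratio_per_unit),
    censoring_rate = eff$censoring_rate,
    followup_cap_months = eff$followup_cap_months,
    margin_mm = eff$margin_mm,
    recurrence_station_weights = unlist(eff$recurrence_station_weights),
    p_recurrence_at_gross = eff$p_recurrence_at_gross)
  depth <- unlist(x$depth_grid)
  depth[depth < 0] <- Inf
  run_config(master_seed = x$master_seed, n = x$n,
             grid_shape = unlist(x$grid_shape),
             grid_spacing = unlist(x$grid_spacing),
             gross_disease = x$gross_disease,
             min_overlap_voxels = x$min_overlap_voxels,
             corr_threshold = x$corr_threshold, folds = x$folds,
             rfe = x$rfe, rfe_step = x$rfe_step,
             depth_grid = depth, trees_grid = unlist(x$trees_grid),
             train_fraction = x$train_fraction,
             horizon_months = x$horizon_months,
             group_covariate = x$group_covariate, group_cut = x$group_cut,
             effect = effect)
}

#' Execute the full pipeline into a run directory
#'
#' Runs simulate -> extract -> map-recurrence -> train -> survival and
#' writes `features.csv`, `tally.csv`, `report.json`, `roc.csv`,
#' `survival.json`, the resolved config (`config.yaml`) and a structured
#' per-stage log (`run.log`). Numeric outputs are byte-identical across
#' reruns with the same config; every output carries the MD5 hash of the
#' resolved config (JSON field `config_hash`, `#`-comment header in CSVs).
#' Any stage failure aborts with the stage name and leaves a `FAILED`
#' marker next to the partial outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param write_masks also write each patient's NIfTI masks under
#'   `cohort/`? (off by default: the feature table is what downstream
#'   stages consume).
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `tally`, `report`, `survival`) and `out_dir`.
#' @export
run_all <- function(config = run_config(), out_dir, write_masks = FALSE) {
  validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("run_all config_hash=%s\n", cfg_hash), file = log_path)
  logline <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  }
  fail <- function(stage, e) {
    writeLines(sprintf("FAILED at stage %s: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    ctv_stop("ctv_run_error", "stage '%s' failed: %s", stage, conditionMessage(e))
  }
  stage <- function(name, expr) {
    logline(name, "start")
    r <- tryCatch(expr, error = function(e) fail(name, e))
    logline(name, "done")
    r
  }
  write_csv_hashed <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# config_hash: %s", cfg_hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }

  cohort <- stage("simulate", {
    grid <- voxel_grid(config$grid_shape, config$grid_spacing)
    atlas <- generate_atlas(atlas_spec(grid))
    generate_cohort(config$n, atlas, config$effect,
                    seed = substream_seed(config$master_seed, "simulate"),
                    out_dir = if (write_masks) file.path(out_dir, "cohort") else NULL)
  })

  feats <- stage("extract", {
    f <- extract_cohort_features(cohort, gross_disease = config$gross_disease,
                                 min_overlap_voxels = config$min_overlap_voxels)
    f$relapse <- cohort$features$relapse
    write_csv_hashed(f, "features.csv")
    f
  })

  tally <- stage("map-recurrence", {
    events <- classify_cohort_recurrences(cohort,
                                          gross_disease = config$gross_disease)
    tl <- tally_by_station(events)
    out <- tl$by_station
    out$total <- tl$total
    write_csv_hashed(out, "tally.csv")
    tl
  })

  report <- stage("train", {
    rep <- fit_recurrence_pipeline(
      feats[, c(feature_names())], feats$relapse,
      fraction = config$train_fraction,
      seed = substream_seed(config$master_seed, "train"),
      corr_threshold = config$corr_threshold, rfe = config$rfe,
      folds = config$folds, step = config$rfe_step,
      depth_grid = config$depth_grid, trees_grid = config$trees_grid)
    write_csv_hashed(rep$roc, "roc.csv")
    json <- list(
      config_hash = cfg_hash,
      screening = list(
        n_dropped_correlated = nrow(rep$screening$dropped_correlated),
        dropped_correlated = rep$screening$dropped_correlated,
        rfe_path = rep$screening$rfe_path,
        selected = rep$screening$selected),
      model = list(depth = if (is.finite(rep$model$depth)) rep$model$depth else "unbounded",
                   num_trees = rep$model$num_trees),
      split = rep$split[c("n_train", "n_validation")],
      metrics_train = as.list(rep$metrics_train),
      metrics_validation = as.list(rep$metrics_validation))
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    rep
  })

  surv <- stage("survival", {
    oc <- cohort$outcomes
    covar <- vapply(cohort$patients,
                    function(p) p$record[[config$group_covariate]], numeric(1))
    grp <- ifelse(covar >= config$group_cut,
                  sprintf(">=%g", config$group_cut),
                  sprintf("<%g", config$group_cut))
    contrast <- local_control_contrast(oc$time, oc$event, grp,
                                       horizon_months = config$horizon_months)
    ct <- table(factor(grp), factor(oc$event, levels = c(0, 1)))
    cont <- contingency_2x2(ct[1, 1], ct[1, 2], ct[2, 1], ct[2, 2])
    json <- list(
      config_hash = cfg_hash,
      group_covariate = config$group_covariate, group_cut = config$group_cut,
      horizon_months = config$horizon_months,
      n = as.list(setNames(as.integer(contrast$n), names(contrast$n))),
      lc_rate = as.list(contrast$lc_rate),
      log_rank = contrast$log_rank[c("chisq", "p_value")],
      cox = contrast$cox[c("hr", "ci_lower", "ci_upper", "p_value")],
      contingency = cont)
    jsonlite::write_json(json, file.path(out_dir, "survival.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    # km curves for plotting/reporting
    km_df <- do.call(rbind, lapply(names(contrast$km), function(l) {
      k <- contrast$km[[l]]
      data.frame(group = l, time = k$time, surv = k$surv,
                 n_risk = k$n_risk, n_event = k$n_event)
    }))
    write_csv_hashed(km_df, "km.csv")
    contrast
  })

  logline("run", "complete")
  invisible(list(cohort = cohort, features = feats, tally = tally,
                 report = report, survival = surv, out_dir = out_dir,
                 config_hash = cfg_hash))
}

#' Render a human-readable run summary
#'
#' Markdown summary of a completed [run_all()] directory: the 16-row
#' station recurrence tally with its Total row, the train/validation
#' metric grid, and the local-control contrast.
#'
#' @param out_dir a completed run directory.
#' @param file optional path to also write the markdown to.
#' @return the markdown, invisibly, as a character vector of lines.
#' @export
render_report <- function(out_dir, file = NULL) {
  need <- c("tally.csv", "report.json", "survival.json", "features.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    ctv_stop("ctv_report_error", "missing: %s", paste(missing, collapse = ", "))
  }
  tally <- read.csv(file.path(out_dir, "tally.csv"), comment.char = "#",
                    colClasses = c(station_label = "character"))
  rep <- jsonlite::read_json(file.path(out_dir, "report.json"),
                             simplifyVector = TRUE)
  surv <- jsonlite::read_json(file.path(out_dir, "survival.json"),
                              simplifyVector = TRUE)
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.3f", x))
  lines <- c(
    "# Recurrence analysis run summary",
    "",
    sprintf("Config hash: `%s`", rep$config_hash),
    "",
    "## Station-level recurrence tally",
    "",
    "| Area | Number of regional recurrence | Actual/idea area proportion (mean) | Actual/idea area proportion (range) | GTV affected area | CTV-GTV recurrence cases |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %s | %s | %d | %d |",
            tally$station_label, tally$n_events,
            fmt(tally$mean_actual_over_idea),
            ifelse(is.na(tally$min_actual_over_idea), "-",
                   sprintf("%s-%s", fmt(tally$min_actual_over_idea),
                           fmt(tally$max_actual_over_idea))),
            tally$n_gtv_affected, tally$n_ctv_minus_gtv),
    sprintf("| Total | %d |  |  | %d | %d |",
            tally$total[1], sum(tally$n_gtv_affected), sum(tally$n_ctv_minus_gtv)),
    "",
    "## Prediction model",
    "",
    sprintf("Selected %d features; depth %s, %s trees.",
            length(rep$screening$selected), rep$model$depth, rep$model$num_trees),
    "",
    "| Metric | Training Set | Validation Set |",
    "|---|---|---|",
    sprintf("| %s | %.3f | %.3f |",
            c("Accuracy", "AUC", "Precision", "Recall", "F1-Score"),
            unlist(rep$metrics_train[c("accuracy", "auc", "precision", "recall", "f1")]),
            unlist(rep$metrics_validation[c("accuracy", "auc", "precision", "recall", "f1")])),
    "",
    "## Local control",
    "",
    sprintf("Grouped by %s at %g; local-control rate at %g months: %s.",
            surv$group_covariate, surv$group_cut, surv$horizon_months,
            paste(sprintf("%s: %.1f%%", names(surv$lc_rate),
                          100 * unlist(surv$lc_rate)), collapse = ", ")),
    sprintf("Log-rank chi-square %.3f (p = %.4f); hazard ratio %.3f (95%% CI %.3f-%.3f, p = %.4f).",
            surv$log_rank$chisq, surv$log_rank$p_value,
            surv$cox$hr, surv$cox$ci_lower, surv$cox$ci_upper, surv$cox$p_value)
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
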