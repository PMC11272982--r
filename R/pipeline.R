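#' Run the full risk-prediction pipeline on a dataset
#'
#' Orchestrates the stages in the leakage-safe order: stratified three-way
#' partition, chained-equation imputation, label encoding, standard scaling
#' (fit on train), IQR capping (fences from train), SMOTE on the training
#' partition only (when the imbalance trigger fires), two-tier feature
#' selection on the training partition, babysitting grid tuning (refit on
#' train + validation), and a single final test evaluation.
#'
#' @param ds a [tabular_dataset()] (raw: may contain missing cells and
#'   categorical columns)
#' @param imbalance_threshold trigger for SMOTE (default 0.1: resample when
#'   minority/majority < 0.9)
#' @param grid a [hyper_grid()]
#' @param metric tuning metric (`"accuracy"`, `"f1"`, `"auc"`)
#' @param goa_cfg,fitness_cfg,ridge_cfg,smote_cfg,mice_cfg stage configurations
#' @param select_features run the two-tier selector (default TRUE)
#' @param seed master seed; per-stage seeds are derived from it
#' @return list with `selected_features`, `score_table`, `tuning`
#'   (a [babysit()] result incl. the final model and test metrics),
#'   `imbalance`, and the fitted preprocessing parameters
#' @export
run_pipeline <- function(ds, imbalance_threshold = 0.1,
                         grid = hyper_grid(),
                         metric = "accuracy",
                         goa_cfg = NULL, fitness_cfg = NULL,
                         ridge_cfg = ridge_config(),
                         smote_cfg = NULL, mice_cfg = NULL,
                         select_features = TRUE,
                         seed = 0) {
  seed <- as.integer(seed)
  if (is.null(goa_cfg)) goa_cfg <- goa_config(seed = seed + 10L)
  if (is.null(fitness_cfg)) fitness_cfg <- fitness_config(seed = seed + 11L)
  if (is.null(smote_cfg)) smote_cfg <- smote_config(seed = seed + 12L)
  if (is.null(mice_cfg)) mice_cfg <- mice_config(seed = seed + 13L)

  parts <- make_partitions(ds, seed = seed)
  # impute each partition with models fit on its own rows (no test leakage)
  parts <- lapply(parts, mice_impute, cfg = mice_cfg)

  enc <- label_encode(parts$train)
  parts$train <- enc$dataset
  parts$validation <- label_encode(parts$validation, enc$encoding)$dataset
  parts$test <- label_encode(parts$test, enc$encoding)$dataset

  scaler <- fit_scaler(parts$train)
  parts <- lapply(parts, apply_scaler, params = scaler)

  bounds <- fit_outlier_bounds(parts$train)
  parts <- lapply(parts, cap_outliers, bounds = bounds)

  imb <- imbalance_report(parts$train$target, imbalance_threshold)
  if (imb$triggered) parts$train <- smote_resample(parts$train, smote_cfg)

  if (select_features) {
    sel <- gol2_select(parts$train, goa_cfg, fitness_cfg, ridge_cfg)
    feats <- sel$selected
    score_table <- sel$table
  } else {
    feats <- feature_names(parts$train)
    score_table <- NULL
  }
  tune <- babysit(take_features(parts$train, feats),
                  take_features(parts$validation, feats),
                  take_features(parts$test, feats),
                  grid = grid, metric = metric, seed = seed + 20L)

  list(selected_features = feats, score_table = score_table,
       tuning = tune, imbalance = imb,
       preprocessing = list(encoding = enc$encoding, scaler = scaler,
                            bounds = bounds))
}

#' Serialize fitted preprocessing parameters to JSON
#' @param prep the `preprocessing` element of a [run_pipeline()] result
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_preprocessing_json <- function(prep, path) {
  jsonlite::write_json(
    list(encoding = lapply(prep$encoding, as.list),
         scaler = lapply(unclass(prep$scaler), as.list),
         bounds = lapply(unclass(prep$bounds), as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
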