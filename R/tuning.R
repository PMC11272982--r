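#' Hyperparameter grid for the babysitting tuner
#'
#' Defaults follow the trials actually run in the tuning ledger this mirrors:
#' `n_estimators` in {50, 100, 200} crossed with `learning_rate` in
#' {0.1, 0.5, 1.0}.
#'
#' @param n_estimators positive integers, no duplicates
#' @param learning_rate reals in (0, 1], no duplicates
#' @return an object of class `hyper_grid`
#' @export
hyper_grid <- function(n_estimators = c(50, 100, 200),
                       learning_rate = c(0.1, 0.5, 1.0)) {
  stopifnot(length(n_estimators) >= 1, length(learning_rate) >= 1,
            !anyDuplicated(n_estimators), !anyDuplicated(learning_rate),
            all(n_estimators >= 1), all(learning_rate > 0),
            all(learning_rate <= 1))
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate),
            class = "hyper_grid")
}

#' Babysitting grid search with a trial ledger
#'
#' Walks the grid exhaustively in row-major order (`n_estimators` outer,
#' `learning_rate` inner), training on the training partition and scoring each
#' trial on the validation partition; trials are numbered from 0 in a ledger.
#' The best trial (argmax of the metric, ties broken by lowest trial number)
#' is refit on train + validation and evaluated exactly once on the test
#' partition. Fully deterministic given the seed; all metrics are on the
#' [0, 1] scale.
#'
#' @param train,validation,test disjoint fully numeric [tabular_dataset()]s
#' @param grid a [hyper_grid()]
#' @param metric `"accuracy"`, `"f1"` or `"auc"`
#' @param seed integer seed passed to each model fit
#' @param trial_fn optional override `function(n_estimators, learning_rate,
#'   train, validation) -> metric value` (used to inject mocks in tests)
#' @param final_fn optional override `function(n_estimators, learning_rate,
#'   train_plus_validation, test) -> list(model, metrics)`
#' @return an object of class `tuning_result`: `ledger` (data.frame with
#'   `trial_no`, `n_estimators`, `learning_rate`, `metric`), `best_trial`
#'   (0-based), `best_hyperparameters`, `final_model`, `test_metrics`
#' @export
babysit <- function(train, validation, test, grid = hyper_grid(),
                    metric = c("accuracy", "f1", "auc"), seed = 0,
                    trial_fn = NULL, final_fn = NULL) {
  metric <- match.arg(metric)
  for (part in list(train, validation, test)) {
    if (n_samples(part) == 0) stop("empty partition", call. = FALSE)
  }
  metric_of <- function(model, ds) {
    rep <- evaluate_model(model, ds)
    rep[[metric]]
  }
  if (is.null(trial_fn)) {
    trial_fn <- function(ne, lr, train, validation) {
      model <- abdf_fit(train, cfg = abdf_config(n_estimators = ne,
                                                 learning_rate = lr,
                                                 seed = seed))
      metric_of(model, validation)
    }
  }
  if (is.null(final_fn)) {
    final_fn <- function(ne, lr, fit_data, test) {
      model <- abdf_fit(fit_data, cfg = abdf_config(n_estimators = ne,
                                                    learning_rate = lr,
                                                    seed = seed))
      list(model = model, metrics = evaluate_model(model, test))
    }
  }
  combos <- expand.grid(learning_rate = grid$learning_rate,
                        n_estimators = grid$n_estimators)  # ne outer, lr inner
  combos <- combos[, c("n_estimators", "learning_rate")]
  vals <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    vals[i] <- trial_fn(combos$n_estimators[i], combos$learning_rate[i],
                        train, validation)
  }
  ledger <- data.frame(trial_no = seq_len(nrow(combos)) - 1L,
                       n_estimators = combos$n_estimators,
                       learning_rate = combos$learning_rate,
                       metric = vals)
  names(ledger)[4] <- metric
  best <- which.max(vals)   # which.max takes the first maximum: lowest trial_no
  best_hp <- list(n_estimators = combos$n_estimators[best],
                  learning_rate = combos$learning_rate[best])
  fit_data <- bind_datasets(train, validation)
  final <- final_fn(best_hp$n_estimators, best_hp$learning_rate, fit_data, test)
  structure(list(ledger = ledger, best_trial = best - 1L,
                 best_hyperparameters = best_hp,
                 final_model = final$model, test_metrics = final$metrics),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d trials; best trial %d (n_estimators = %d, learning_rate = %g)\n",
              nrow(x$ledger), x$best_trial,
              x$best_hyperparameters$n_estimators,
              x$best_hyperparameters$learning_rate))
  if (!is.null(x$test_metrics)) print(x$test_metrics)
  invisible(x)
}

#' Write a tuning ledger to CSV
#' @param result a [babysit()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ledger <- function(result, path) {
  utils::write.csv(result$ledger, path, row.names = FALSE)
  invisible(path)
}
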