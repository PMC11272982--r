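#' Confusion matrix with class 1 as positive
#'
#' @param y_true,y_pred equal-length 0/1 vectors
#' @return an object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn`
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  stopifnot(all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_matrix")
}

#' ROC curve by threshold sweep
#'
#' Points are cumulated over score thresholds from high to low; tied scores
#' are grouped, so under trapezoidal integration ties contribute half-steps
#' and label-independent scores give an AUC of exactly 0.5. The curve starts
#' at (0,0) and ends at (1,1) with both coordinates non-decreasing.
#'
#' @param y_true 0/1 labels (both classes present)
#' @param scores real-valued scores, higher = more positive
#' @return an object of class `roc_curve`: data.frame of `(fpr, tpr)` points
#'   with an `auc` attribute
#' @export
roc_curve <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  grp_end <- which(c(diff(s) != 0, TRUE))   # last index of each tie group
  tpr <- c(0, cumsum(y == 1)[grp_end] / n_pos, 1)
  fpr <- c(0, cumsum(y == 0)[grp_end] / n_neg, 1)
  pts <- unique(data.frame(fpr = fpr, tpr = tpr))
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(pts, auc = auc, class = c("roc_curve", "data.frame"))
}

#' Classification metrics report
#'
#' Computes accuracy, precision, recall, F1 (harmonic mean) from a confusion
#' matrix, and the trapezoidal AUC from scores when provided. Any ratio with a
#' zero denominator is reported as 0 and the affected metric is listed in the
#' `undefined` attribute instead of raising.
#'
#' @param cm a [confusion()] result
#' @param scores optional real scores for the AUC
#' @param y_true labels matching `scores` (required when `scores` given)
#' @return an object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`
#' @export
compute_metrics <- function(cm, scores = NULL, y_true = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  accuracy <- safe_div(cm$tp + cm$tn, n, "accuracy")
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(!is.null(y_true))
    auc <- attr(roc_curve(y_true, scores), "auc")
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, auc = auc),
            undefined = undefined, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f | precision %.4f | recall %.4f | f1 %.4f | auc %s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Evaluate a classifier on a dataset
#'
#' Convenience wrapper: predicts labels and scores with the model and returns
#' a [compute_metrics()] report.
#'
#' @param model an [abdf_fit()] model
#' @param ds a fully numeric, complete [tabular_dataset()]
#' @return a `metrics_report`
#' @export
evaluate_model <- function(model, ds) {
  X <- feature_matrix(ds)
  pred <- stats::predict(model, X)
  score <- stats::predict(model, X, type = "score")
  compute_metrics(confusion(ds$target, pred), scores = score,
                  y_true = ds$target)
}

#' Write a model-comparison report to CSV and JSON
#'
#' One row per model, fixed column order `model, accuracy, precision, recall,
#' f1, auc`. The JSON twin is written next to the CSV.
#'
#' @param results non-empty named list of `metrics_report`s
#' @param path output CSV path (the JSON goes to the same path with a `.json`
#'   extension)
#' @return the CSV path, invisibly
#' @export
write_report <- function(results, path) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(model = nm, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, auc = r$auc,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(rows, sub("\\.csv$", ".json", paste0(sub("\\.csv$", "", path), ".csv")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
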