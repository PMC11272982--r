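#' Label-encode categorical columns to integers
#'
#' Each categorical level is mapped to a distinct integer `0..L-1` in
#' lexicographic (C-locale) level order, a deterministic convention; the
#' encoded columns become numeric. The returned encoding map supports the
#' inverse transform and re-application to new data.
#'
#' @param ds a [tabular_dataset()]
#' @param encoding optional encoding map from a previous [label_encode()] call;
#'   when supplied, it is applied as-is and unseen levels raise an error.
#' @return a list with `dataset` (encoded [tabular_dataset()]) and `encoding`
#'   (named list: column -> named integer vector level -> code).
#' @export
label_encode <- function(ds, encoding = NULL) {
  cat_cols <- ds$columns$name[ds$columns$kind == "categorical"]
  if (is.null(encoding)) {
    encoding <- lapply(cat_cols, function(cn) {
      lv <- sort(ds$levels[[cn]], method = "radix")
      stats::setNames(seq_along(lv) - 1L, lv)
    })
    names(encoding) <- cat_cols
  }
  out <- ds
  for (cn in intersect(cat_cols, names(encoding))) {
    map <- encoding[[cn]]
    vals <- ds$data[[cn]]
    unseen <- setdiff(unique(vals[!is.na(vals)]), names(map))
    if (length(unseen) > 0) {
      stop(sprintf("column '%s' has level(s) unseen by the encoding: %s",
                   cn, paste(unseen, collapse = ", ")), call. = FALSE)
    }
    out$data[[cn]] <- as.numeric(unname(map[vals]))
    out$columns$kind[out$columns$name == cn] <- "numeric"
  }
  out$levels <- ds$levels            # kept for the inverse transform
  list(dataset = out, encoding = encoding)
}

#' Invert a label encoding
#' @param ds an encoded [tabular_dataset()]
#' @param encoding the map returned by [label_encode()]
#' @return a [tabular_dataset()] with the original level strings restored
#' @export
label_decode <- function(ds, encoding) {
  out <- ds
  for (cn in names(encoding)) {
    map <- encoding[[cn]]
    inv <- stats::setNames(names(map), as.character(unname(map)))
    out$data[[cn]] <- unname(inv[as.character(ds$data[[cn]])])
    out$columns$kind[out$columns$name == cn] <- "categorical"
  }
  out
}

#' Fit standard-scaling parameters on (training) data
#'
#' Computes, for every numeric column, the mean `mu` and population standard
#' deviation `sigma` (divide by n), the plain-sigma convention of the
#' `(x - mu) / sigma` standardization. Fit on the training partition only.
#'
#' @param ds a [tabular_dataset()]
#' @return an object of class `scaler_params`: named list of `c(mu, sigma)`
#' @export
fit_scaler <- function(ds) {
  num_cols <- ds$columns$name[ds$columns$kind == "numeric"]
  params <- lapply(num_cols, function(cn) {
    x <- ds$data[[cn]]
    x <- x[!is.na(x)]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    c(mu = mu, sigma = sigma)
  })
  names(params) <- num_cols
  structure(params, class = "scaler_params")
}

#' Apply standard scaling
#'
#' Transforms each numeric column as `(x - mu) / sigma`; columns whose fitted
#' `sigma` is zero map to all zeros by convention.
#'
#' @param ds a [tabular_dataset()]
#' @param params a [fit_scaler()] result (fit on training data)
#' @return the scaled [tabular_dataset()]
#' @export
apply_scaler <- function(ds, params) {
  out <- ds
  for (cn in intersect(names(params), ds$columns$name)) {
    p <- params[[cn]]
    x <- ds$data[[cn]]
    out$data[[cn]] <- if (p[["sigma"]] > 0) (x - p[["mu"]]) / p[["sigma"]] else
      ifelse(is.na(x), NA_real_, 0)
  }
  out
}
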