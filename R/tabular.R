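#' Tabular dataset with a binary target
#'
#' The container every pipeline stage consumes and produces: an ordered set of
#' feature columns (numeric or categorical), a binary 0/1 target, and
#' per-column kind metadata. Missing feature cells are represented by `NA`;
#' the target must be fully observed.
#'
#' @param data data.frame of feature columns. Numeric columns must be numeric
#'   vectors; categorical columns character vectors.
#' @param target integer/numeric vector of 0s and 1s, one per row of `data`.
#' @param kinds optional character vector (`"numeric"` or `"categorical"`),
#'   one per column of `data`; inferred from column types when omitted.
#' @param levels optional named list giving the declared level set of each
#'   categorical column; inferred from observed values when omitted.
#' @return An object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(data, target, kinds = NULL, levels = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(kinds)) {
    kinds <- vapply(data, function(col) {
      if (is.numeric(col)) "numeric" else "categorical"
    }, character(1))
  }
  if (length(kinds) != ncol(data)) {
    stop("`kinds` must have one entry per feature column", call. = FALSE)
  }
  kinds <- unname(kinds)
  if (!all(kinds %in% c("numeric", "categorical"))) {
    stop("column kinds must be 'numeric' or 'categorical'", call. = FALSE)
  }
  if (length(target) != nrow(data)) {
    stop("`target` length must equal the number of rows", call. = FALSE)
  }
  if (anyNA(target) || !all(target %in% c(0L, 1L))) {
    stop("`target` must be fully observed and take values in {0, 1}",
         call. = FALSE)
  }
  cat_cols <- names(data)[kinds == "categorical"]
  if (is.null(levels)) {
    levels <- lapply(data[cat_cols], function(col) {
      sort(unique(col[!is.na(col)]), method = "radix")
    })
    names(levels) <- cat_cols
  }
  for (cn in cat_cols) {
    col <- data[[cn]]
    if (!is.character(col)) data[[cn]] <- as.character(col)
    bad <- !is.na(data[[cn]]) & !(data[[cn]] %in% levels[[cn]])
    if (any(bad)) {
      stop(sprintf("column '%s' contains values outside its declared levels",
                   cn), call. = FALSE)
    }
  }
  structure(
    list(
      data = data,
      columns = data.frame(name = names(data), kind = kinds,
                           stringsAsFactors = FALSE),
      levels = levels,
      target = as.integer(target)
    ),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows x %d features (%d numeric, %d categorical)\n",
              nrow(x$data), ncol(x$data),
              sum(x$columns$kind == "numeric"),
              sum(x$columns$kind == "categorical")))
  cat(sprintf("  target: %d zeros / %d ones; missing feature cells: %d\n",
              sum(x$target == 0L), sum(x$target == 1L),
              sum(is.na(x$data))))
  invisible(x)
}

#' Number of rows in a tabular dataset
#' @param ds a [tabular_dataset()]
#' @return integer row count
#' @export
n_samples <- function(ds) nrow(ds$data)

#' Feature names of a tabular dataset
#' @param ds a [tabular_dataset()]
#' @return character vector of column names, in order
#' @export
feature_names <- function(ds) ds$columns$name

#' Kinds ("numeric"/"categorical") of the feature columns
#' @param ds a [tabular_dataset()]
#' @return named character vector
#' @export
feature_kinds <- function(ds) stats::setNames(ds$columns$kind, ds$columns$name)

#' Numeric feature matrix of a fully numeric dataset
#'
#' Fails if any column is still categorical (encode first) or any cell is
#' missing (impute first).
#' @param ds a [tabular_dataset()]
#' @return numeric matrix, one column per feature
#' @export
feature_matrix <- function(ds) {
  if (any(ds$columns$kind != "numeric")) {
    stop("dataset still has categorical columns; run label_encode() first",
         call. = FALSE)
  }
  if (anyNA(ds$data)) {
    stop("dataset has missing cells; run mice_impute() first", call. = FALSE)
  }
  as.matrix(ds$data)
}

#' Subset the rows of a tabular dataset
#' @param ds a [tabular_dataset()]
#' @param idx integer or logical row index
#' @return a [tabular_dataset()] with the selected rows
#' @export
take_rows <- function(ds, idx) {
  out <- ds
  out$data <- ds$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$target <- ds$target[idx]
  out
}

#' Keep a subset of feature columns
#' @param ds a [tabular_dataset()]
#' @param cols character vector of feature names to keep
#' @return a [tabular_dataset()] restricted to `cols`
#' @export
take_features <- function(ds, cols) {
  miss <- setdiff(cols, feature_names(ds))
  if (length(miss) > 0) {
    stop("unknown feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- match(cols, ds$columns$name)
  out <- ds
  out$data <- ds$data[, cols, drop = FALSE]
  out$columns <- ds$columns[keep, , drop = FALSE]
  rownames(out$columns) <- NULL
  out$levels <- ds$levels[intersect(names(ds$levels), cols)]
  out
}

#' Stack two datasets with identical schemas row-wise
#' @param a,b [tabular_dataset()] objects with identical columns
#' @return the combined [tabular_dataset()]
#' @export
bind_datasets <- function(a, b) {
  if (!identical(a$columns, b$columns)) {
    stop("datasets have different schemas", call. = FALSE)
  }
  tabular_dataset(rbind(a$data, b$data), c(a$target, b$target),
                  kinds = a$columns$kind, levels = a$levels)
}

#' Write a dataset to CSV (with a JSON sidecar describing the schema)
#'
#' Missing cells are written as empty fields. The sidecar `<path>.json`
#' records column kinds and categorical levels so the file round-trips.
#' @param ds a [tabular_dataset()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_dataset_csv <- function(ds, path) {
  df <- ds$data
  df$target <- ds$target
  utils::write.csv(df, path, row.names = FALSE, na = "")
  sidecar <- list(columns = ds$columns, levels = ds$levels)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset_csv()]
#' @param path CSV path (a `<path>.json` sidecar must exist)
#' @return a [tabular_dataset()]
#' @export
read_dataset_csv <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "")
  target <- df$target
  df$target <- NULL
  df <- df[, sidecar$columns$name, drop = FALSE]
  for (i in seq_len(ncol(df))) {
    if (sidecar$columns$kind[i] == "numeric") {
      df[[i]] <- as.numeric(df[[i]])
    } else {
      df[[i]] <- as.character(df[[i]])
    }
  }
  levels <- sidecar$levels
  if (length(levels) == 0) levels <- stats::setNames(list(), character(0))
  tabular_dataset(df, target, kinds = sidecar$columns$kind, levels = levels)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
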