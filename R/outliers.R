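#' Fit interquartile-range outlier fences
#'
#' For every numeric column computes the quartiles Q1 and Q3 by
#' linear-interpolation quantiles (type 7), the IQR = Q3 - Q1, and the Tukey
#' fences `lower = Q1 - 1.5 IQR`, `upper = Q3 + 1.5 IQR`. A column with fewer
#' than two observed values degenerates to fences at that single value.
#' Fit on training data only and reuse on held-out partitions.
#'
#' @param ds a [tabular_dataset()]
#' @return an object of class `outlier_bounds`: per numeric column a named
#'   vector `c(q1, q3, iqr, lower, upper)`
#' @export
fit_outlier_bounds <- function(ds) {
  num_cols <- ds$columns$name[ds$columns$kind == "numeric"]
  bounds <- lapply(num_cols, function(cn) {
    x <- ds$data[[cn]]
    x <- x[!is.na(x)]
    if (length(x) < 2) {
      v <- if (length(x) == 1) x else NA_real_
      return(c(q1 = v, q3 = v, iqr = 0, lower = v, upper = v))
    }
    q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
    iqr <- q[2] - q[1]
    c(q1 = q[1], q3 = q[2], iqr = iqr,
      lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  })
  names(bounds) <- num_cols
  structure(bounds, class = "outlier_bounds")
}

#' Cap numeric values into the fitted IQR fences
#'
#' Clips every numeric cell into `[lower, upper]` per column. Categorical
#' columns and the target are untouched; capping with fences fit once is
#' idempotent.
#'
#' @param ds a [tabular_dataset()]
#' @param bounds a [fit_outlier_bounds()] result
#' @return the capped [tabular_dataset()]
#' @export
cap_outliers <- function(ds, bounds) {
  out <- ds
  for (cn in intersect(names(bounds), ds$columns$name)) {
    b <- bounds[[cn]]
    if (is.na(b[["lower"]])) next
    out$data[[cn]] <- pmin(pmax(ds$data[[cn]], b[["lower"]]), b[["upper"]])
  }
  out
}
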