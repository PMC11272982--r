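#' Class-imbalance report
#'
#' Computes the imbalance ratio as minority count / majority count, the
#' direction under which the 410/508 class split yields 0.8071, and flags the
#' dataset for resampling when `ratio < 1 - threshold`.
#'
#' @param target binary 0/1 vector (both classes must be present)
#' @param threshold imbalance threshold in `[0, 1]` (default 0.1, i.e. trigger
#'   when the ratio falls below 0.9)
#' @return an object of class `imbalance_report` with fields
#'   `count_minority`, `count_majority`, `minority_class`, `ratio`,
#'   `threshold`, `triggered`
#' @export
imbalance_report <- function(target, threshold = 0.1) {
  stopifnot(all(target %in% c(0, 1)), threshold >= 0, threshold <= 1)
  n0 <- sum(target == 0)
  n1 <- sum(target == 1)
  if (n0 == 0 || n1 == 0) {
    stop("target has a single class; imbalance ratio undefined", call. = FALSE)
  }
  cmin <- min(n0, n1)
  cmaj <- max(n0, n1)
  ratio <- cmin / cmaj
  structure(list(count_minority = cmin, count_majority = cmaj,
                 minority_class = if (n0 <= n1) 0L else 1L,
                 ratio = ratio, threshold = threshold,
                 triggered = ratio < 1 - threshold),
            class = "imbalance_report")
}

#' @export
print.imbalance_report <- function(x, ...) {
  cat(sprintf("<imbalance_report> minority %d / majority %d, ratio %.4f (threshold %.2f) -> %s\n",
              x$count_minority, x$count_majority, x$ratio, x$threshold,
              if (x$triggered) "resampling triggered" else "balanced enough"))
  invisible(x)
}

#' SMOTE configuration
#' @param k_neighbors number of nearest minority neighbors (default 5)
#' @param seed integer seed
#' @return an object of class `smote_config`
#' @export
smote_config <- function(k_neighbors = 5, seed = 0) {
  stopifnot(k_neighbors >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors), seed = as.integer(seed)),
            class = "smote_config")
}

#' SMOTE minority oversampling
#'
#' Oversamples the minority class to exactly the majority count. Each synthetic
#' row is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0,1)` and `x_nn` one of
#' the `k` nearest minority neighbors of the parent `x_i` under Euclidean
#' distance on the (already encoded and scaled) numeric features. Original
#' rows are preserved verbatim, synthetic rows appended after them; the result
#' carries a `smote_lineage` attribute recording `(parent, neighbor, u)` for
#' every synthetic row. Deterministic given the seed.
#'
#' If the minority count is `<= k_neighbors`, `k` is reduced to count - 1 with
#' a warning; a single minority row is an error (no neighbor to interpolate
#' toward).
#'
#' @param ds a fully numeric, complete [tabular_dataset()]
#' @param cfg a [smote_config()]
#' @return the balanced [tabular_dataset()]
#' @export
smote_resample <- function(ds, cfg = smote_config()) {
  X <- feature_matrix(ds)
  y <- ds$target
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present", call. = FALSE)
  if (n0 == n1) return(ds)
  minority <- if (n0 < n1) 0L else 1L
  idx_min <- which(y == minority)
  n_min <- length(idx_min)
  n_new <- abs(n1 - n0)
  if (n_min == 1) stop("minority class has a single row; SMOTE needs a neighbor",
                       call. = FALSE)
  k <- cfg$k_neighbors
  if (n_min <= k) {
    k <- n_min - 1L
    warning(sprintf("minority count %d <= k_neighbors; reducing k to %d",
                    n_min, k))
  }
  Xmin <- X[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(Xmin))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(row) order(row)[seq_len(k)]))

  with_local_seed(cfg$seed, {
    parent <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(k, n_new, replace = TRUE)
    u <- stats::runif(n_new)
    neighbor <- nn[cbind(parent, pick)]
    synth <- Xmin[parent, , drop = FALSE] +
      u * (Xmin[neighbor, , drop = FALSE] - Xmin[parent, , drop = FALSE])
    new_df <- as.data.frame(synth)
    names(new_df) <- feature_names(ds)
    out <- tabular_dataset(rbind(ds$data, new_df),
                           c(y, rep(minority, n_new)),
                           kinds = ds$columns$kind, levels = ds$levels)
    attr(out, "smote_lineage") <- data.frame(
      parent = idx_min[parent], neighbor = idx_min[neighbor], u = u)
    out
  })
}
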