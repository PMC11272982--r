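#' Ridge regression under the loss MSE + alpha * sum(theta^2)
#'
#' Minimizes `mean((y - X theta)^2) + alpha * sum(theta^2)` with no intercept
#' (the caller standardizes `X` and centers `y`). The closed form solves the
#' normal equations `(X'X/n + alpha I) theta = X'y/n`; the gradient solver
#' runs plain gradient descent with a Lipschitz step and the two agree to
#' 1e-6 on well-posed problems.
#'
#' @param X numeric matrix of standardized features
#' @param y centered numeric response
#' @param alpha non-negative regularization weight
#' @param solver `"closed_form"` or `"gradient"`
#' @return numeric coefficient vector, one per column of `X`
#' @export
ridge_fit <- function(X, y, alpha = 1, solver = c("closed_form", "gradient")) {
  solver <- match.arg(solver)
  stopifnot(alpha >= 0, nrow(X) == length(y))
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  A <- crossprod(X) / n + diag(alpha, p)
  b <- crossprod(X, y) / n
  if (solver == "closed_form") {
    theta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(theta) || rcond(A) < 1e-12) {
      if (alpha == 0) {
        stop("X'X is singular with alpha = 0; use alpha > 0 to regularize",
             call. = FALSE)
      }
      stop("ridge system is numerically singular", call. = FALSE)
    }
    return(drop(theta))
  }
  # gradient of the loss: 2 (A theta - b); step 1/L with L = 2 lambda_max(A)
  if (alpha == 0 && rcond(A) < 1e-12) {
    stop("X'X is singular with alpha = 0; use alpha > 0 to regularize",
         call. = FALSE)
  }
  Lc <- 2 * max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  theta <- rep(0, p)
  for (it in seq_len(200000)) {
    grad <- 2 * (A %*% theta - b)
    if (max(abs(grad)) < 1e-10) break
    theta <- theta - drop(grad) / Lc
  }
  drop(theta)
}

#' Ridge re-scoring configuration (tier 2 of the selector)
#'
#' @param alpha regularization weight (default 1.0)
#' @param solver `"closed_form"` or `"gradient"`
#' @param keep_rule `"abs_coef_above"` keeps features with `|theta| >= epsilon`
#'   (ridge coefficients are never exactly zero, so an absolute cut stands in
#'   for "coefficients greater than zero"); `"top_k"` keeps the `k` largest.
#' @param epsilon cut for `"abs_coef_above"` (default 1e-3)
#' @param top_k k for `"top_k"`
#' @return an object of class `ridge_config`
#' @export
ridge_config <- function(alpha = 1.0, solver = c("closed_form", "gradient"),
                         keep_rule = c("abs_coef_above", "top_k"),
                         epsilon = 1e-3, top_k = NULL) {
  solver <- match.arg(solver)
  keep_rule <- match.arg(keep_rule)
  stopifnot(alpha >= 0, epsilon >= 0)
  if (keep_rule == "top_k" && (is.null(top_k) || top_k < 1)) {
    stop("`top_k` must be a positive integer for keep_rule = 'top_k'",
         call. = FALSE)
  }
  structure(list(alpha = alpha, solver = solver, keep_rule = keep_rule,
                 epsilon = epsilon, top_k = top_k),
            class = "ridge_config")
}

#' Re-score a feature subset with ridge coefficients and prune
#'
#' Standardizes the subset columns (population sd), centers the 0/1 target,
#' fits [ridge_fit()], scores each feature by `|theta|`, and keeps features
#' per the config's keep rule. If the rule prunes everything, the single
#' top-scoring feature is kept with a warning.
#'
#' @param subset character vector of feature names (tier-1 survivors)
#' @param ds a fully numeric, complete [tabular_dataset()] (training data)
#' @param cfg a [ridge_config()]
#' @return a `feature_score_table` data.frame with columns
#'   `feature`, `tier`, `score`, `selected`, sorted by descending score
#' @export
l2_rescore <- function(subset, ds, cfg = ridge_config()) {
  stopifnot(length(subset) >= 1)
  X <- feature_matrix(take_features(ds, subset))
  X <- apply(X, 2, function(col) {
    s <- sqrt(mean((col - mean(col))^2))
    if (s > 0) (col - mean(col)) / s else col * 0
  })
  y <- ds$target - mean(ds$target)
  theta <- ridge_fit(X, y, alpha = cfg$alpha, solver = cfg$solver)
  score <- abs(theta)
  keep <- switch(cfg$keep_rule,
    abs_coef_above = score >= cfg$epsilon,
    top_k = rank(-score, ties.method = "first") <= cfg$top_k
  )
  if (!any(keep)) {
    warning("ridge pruning removed every feature; keeping the top-1")
    keep <- rank(-score, ties.method = "first") == 1
  }
  tab <- data.frame(feature = subset, tier = "L2", score = score,
                    selected = keep, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score), ]
  rownames(tab) <- NULL
  class(tab) <- c("feature_score_table", "data.frame")
  tab
}
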