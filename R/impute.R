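#' Configuration for chained-equation imputation
#'
#' @param max_iterations maximum number of sweeps over the incomplete columns
#'   (default 10).
#' @param tolerance convergence threshold: stop when the largest absolute
#'   change of any imputed numeric value between sweeps is at most this.
#' @param noise `"none"` for deterministic conditional-mean imputation, or
#'   `"gaussian_residual"` to add a draw from the fitted model's residual
#'   distribution to each imputed numeric value.
#' @param seed integer seed (used only when `noise = "gaussian_residual"`).
#' @return an object of class `mice_config`
#' @export
mice_config <- function(max_iterations = 10, tolerance = 1e-6,
                        noise = c("none", "gaussian_residual"), seed = 0) {
  noise <- match.arg(noise)
  stopifnot(max_iterations >= 1, tolerance >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, noise = noise, seed = as.integer(seed)),
            class = "mice_config")
}

#' Impute missing cells by chained equations (MICE)
#'
#' Iterates column-by-column over the incomplete columns, regressing each on
#' all other features: ordinary least squares for numeric columns, the
#' majority observed class for categorical columns. Missing cells are first
#' filled with the column mean/mode, then refined each sweep; iteration stops
#' when the largest change of any imputed numeric value falls below
#' `cfg$tolerance` or after `cfg$max_iterations` sweeps. Observed cells are
#' never altered.
#'
#' @param ds a [tabular_dataset()] (the target must be fully observed; this is
#'   enforced by the container).
#' @param cfg a [mice_config()]
#' @return a [tabular_dataset()] with no missing cells
#' @export
mice_impute <- function(ds, cfg = mice_config()) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!inherits(cfg, "mice_config")) stop("`cfg` must be a mice_config", call. = FALSE)
  d <- ncol(ds$data)
  miss <- lapply(ds$data, function(col) which(is.na(col)))
  all_missing <- names(ds$data)[vapply(miss, length, integer(1)) == n_samples(ds)]
  if (length(all_missing) > 0) {
    stop("column(s) entirely missing: ", paste(all_missing, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- which(vapply(miss, length, integer(1)) > 0)
  if (length(incomplete) == 0) return(ds)

  with_local_seed(cfg$seed, {
    work <- ds$data
    # numeric working copy for conditional models: categoricals -> level index
    as_design <- function(df) {
      out <- df
      for (j in seq_len(d)) {
        if (ds$columns$kind[j] == "categorical") {
          out[[j]] <- as.numeric(match(df[[j]], ds$levels[[names(df)[j]]]))
        }
      }
      out
    }
    # initial fill: column mean (numeric) or mode (categorical)
    for (j in incomplete) {
      obs <- work[[j]][-miss[[j]]]
      if (ds$columns$kind[j] == "numeric") {
        work[[j]][miss[[j]]] <- mean(obs)
      } else {
        tab <- sort(table(obs), decreasing = TRUE)
        work[[j]][miss[[j]]] <- names(tab)[1]
      }
    }

    for (iter in seq_len(cfg$max_iterations)) {
      max_change <- 0
      for (j in incomplete) {
        idx <- miss[[j]]
        obs_rows <- setdiff(seq_len(nrow(work)), idx)
        if (ds$columns$kind[j] == "numeric") {
          design <- as_design(work)
          dat <- design
          names(dat) <- paste0("v", seq_len(d))
          dat$.y <- design[[j]]
          form <- stats::as.formula(paste(".y ~",
            paste(names(dat)[setdiff(seq_len(d), j)], collapse = " + ")))
          fit <- stats::lm(form, data = dat[obs_rows, , drop = FALSE])
          pred <- unname(stats::predict(fit, newdata = dat[idx, , drop = FALSE]))
          if (cfg$noise == "gaussian_residual") {
            sigma <- sqrt(sum(stats::residuals(fit)^2) /
                            max(1, length(obs_rows) - 1))
            pred <- pred + stats::rnorm(length(pred), 0, sigma)
          }
          max_change <- max(max_change, abs(pred - work[[j]][idx]))
          work[[j]][idx] <- pred
        } else {
          tab <- sort(table(work[[j]][obs_rows]), decreasing = TRUE)
          work[[j]][idx] <- names(tab)[1]
        }
      }
      if (max_change <= cfg$tolerance) break
    }
    out <- ds
    out$data <- work
    out
  })
}
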