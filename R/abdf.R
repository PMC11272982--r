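#' Weak-learner specification
#'
#' Learners must support per-instance weights and predict labels in {-1, +1}.
#' `"decision_stump"` is an exhaustive one-split threshold classifier;
#' `"depth2_tree"` a depth-2 CART tree (via rpart); `"logistic_unit"` a
#' weighted logistic regression thresholded at 1/2.
#'
#' @param kind learner kind
#' @param ... per-kind settings. For `"decision_stump"`, `criterion` chooses
#'   how the split is picked: `"error"` (default) minimizes the weighted
#'   misclassification error directly, `"gini"` maximizes the CART weighted
#'   Gini improvement with weighted-majority leaves — the rule used by the
#'   common reference boosting implementations, provided for exact
#'   cross-implementation comparisons.
#' @return an object of class `weak_learner_spec`
#' @export
weak_learner_spec <- function(kind = c("decision_stump", "depth2_tree",
                                       "logistic_unit"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, settings = list(...)), class = "weak_learner_spec")
}

#' AdaBoost decision-fusion configuration
#'
#' @param n_estimators number of boosting rounds UT (the tuned grid spans
#'   50-200)
#' @param learning_rate shrinkage multiplier on each round's vote weight, in
#'   (0, 1] (the tuned grid spans 0.1-1)
#' @param learner_pool ordered list of [weak_learner_spec()]s cycled across
#'   rounds; the default single decision stump gives classical discrete
#'   AdaBoost, a heterogeneous pool gives the "decision fusion" of several
#'   decision-maker types
#' @param seed integer seed (used only for the jittered-bootstrap retry when a
#'   round's weighted error is not below one half)
#' @return an object of class `abdf_config`
#' @export
abdf_config <- function(n_estimators = 50, learning_rate = 1.0,
                        learner_pool = list(weak_learner_spec("decision_stump")),
                        seed = 0) {
  stopifnot(n_estimators >= 1, learning_rate > 0, learning_rate <= 1,
            length(learner_pool) >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 learner_pool = learner_pool, seed = as.integer(seed)),
            class = "abdf_config")
}

#' Vote weight of a weak learner from its weighted error
#'
#' `alpha = learning_rate * 0.5 * log((1 - epsilon) / epsilon)`: positive iff
#' the learner beats chance, zero at `epsilon = 0.5`.
#'
#' @param epsilon weighted error in (0, 1)
#' @param learning_rate shrinkage multiplier
#' @return the vote weight alpha
#' @export
learner_weight <- function(epsilon, learning_rate = 1.0) {
  learning_rate * 0.5 * log((1 - epsilon) / epsilon)
}

# --- weak learners ---------------------------------------------------------

# Exhaustive weighted decision stump, CART-style: minimizes the weighted sum
# of child gini impurities over all features and midpoint thresholds; each
# leaf predicts its weighted majority class (ties to -1). Tie-breaks toward
# the first split found (lowest feature index, lowest threshold). This is the
# split rule of standard tree libraries, which makes boosted-stump runs
# directly comparable with theirs.
fit_stump_gini <- function(X, ym, w) {
  n <- nrow(X)
  pos <- ym > 0
  Wp <- sum(w[pos])
  W <- sum(w)
  best <- list(proxy = -Inf)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    cw <- cumsum(w[ord])
    ca <- cumsum((w * pos)[ord])
    ks <- which(diff(xs) > 0)
    if (length(ks) == 0) next
    WL <- cw[ks]; A <- ca[ks]
    WR <- W - WL; B <- Wp - A
    # sklearn-style proxy of the gini improvement (larger is better)
    proxy <- (A^2 + (WL - A)^2) / WL + (B^2 + (WR - B)^2) / WR
    m <- which.max(proxy)
    if (proxy[m] > best$proxy) {
      k <- ks[m]
      best <- list(proxy = proxy[m], feature = j,
                   threshold = (xs[k] + xs[k + 1]) / 2,
                   left = if (A[m] > WL[m] - A[m]) 1 else -1,
                   right = if (B[m] > WR[m] - B[m]) 1 else -1)
    }
  }
  if (!is.finite(best$proxy)) {
    # no valid split (all feature values constant): predict weighted majority
    maj <- if (Wp > W - Wp) 1 else -1
    best <- list(feature = 1L, threshold = -Inf, left = maj, right = maj)
  }
  structure(best[c("feature", "threshold", "left", "right")],
            class = "stump_gini")
}

predict_stump_gini <- function(h, X) {
  ifelse(X[, h$feature] > h$threshold, h$right, h$left)
}

# Exhaustive weighted decision stump. Predicts +1 on one side of a threshold
# on one feature. Minimizes the weighted 0-1 error over all features,
# thresholds (midpoints between distinct sorted values, plus the all-one-side
# cuts) and both polarities; ties break toward the lowest feature index, then
# the lowest threshold, polarity +1 first (so refits are deterministic).
fit_stump <- function(X, ym, w) {
  n <- nrow(X)
  best <- list(err = Inf)
  wy_pos <- w * (ym > 0)
  wy_neg <- w * (ym < 0)
  Wn <- sum(wy_neg)
  Wp <- sum(wy_pos)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    Apos <- cumsum(wy_pos[ord])   # weight of +1 labels at or below position k
    Bneg <- cumsum(wy_neg[ord])
    distinct <- which(diff(xs) > 0)
    ks <- c(0L, distinct, n)      # cut after position k (0 = all right side)
    thr <- c(xs[1] - 1, (xs[distinct] + xs[distinct + 1]) / 2, xs[n] + 1)
    A <- c(0, Apos[distinct], Wp)
    B <- c(0, Bneg[distinct], Wn)
    err_right <- A + (Wn - B)     # predict +1 when x > thr
    err_left <- Wp - A + B        # predict +1 when x <= thr
    for (pol in c(1, -1)) {
      errs <- if (pol == 1) err_right else err_left
      m <- which.min(errs)
      if (errs[m] < best$err - 1e-15) {
        best <- list(err = errs[m], feature = j, threshold = thr[m],
                     polarity = pol)
      }
    }
  }
  structure(best[c("feature", "threshold", "polarity")], class = "stump")
}

predict_stump <- function(h, X) {
  side <- X[, h$feature] > h$threshold
  ifelse(side, h$polarity, -h$polarity)
}

fit_weak <- function(spec, X, ym, w) {
  switch(spec$kind,
    decision_stump = {
      crit <- spec$settings$criterion
      if (!is.null(crit) && crit == "gini") fit_stump_gini(X, ym, w) else
        fit_stump(X, ym, w)
    },
    depth2_tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        stop("depth2_tree learners require the 'rpart' package", call. = FALSE)
      }
      df <- as.data.frame(X)
      df$.y <- factor(ym, levels = c(-1, 1))
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 2, cp = 0,
                                                         minsplit = 2,
                                                         minbucket = 1,
                                                         xval = 0))
      structure(list(fit = fit), class = "depth2_tree")
    },
    logistic_unit = {
      df <- as.data.frame(X)
      df$.y <- (ym + 1) / 2
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::quasibinomial(),
                   weights = w))
      structure(list(fit = fit), class = "logistic_unit")
    }
  )
}

predict_weak <- function(h, X) {
  if (inherits(h, "stump")) return(predict_stump(h, X))
  if (inherits(h, "stump_gini")) return(predict_stump_gini(h, X))
  df <- as.data.frame(X)
  if (inherits(h, "depth2_tree")) {
    p <- stats::predict(h$fit, newdata = df, type = "class")
    return(ifelse(p == "1", 1, -1))
  }
  p <- stats::predict(h$fit, newdata = df, type = "response")
  ifelse(p > 0.5, 1, -1)
}

# --- boosting --------------------------------------------------------------

#' Fit an AdaBoost decision-fusion ensemble
#'
#' Initializes instance weights at 1/n; each round fits the next learner from
#' the pool under the current weights, computes the weighted error
#' `epsilon_t`, the vote weight `alpha_t = lr * 0.5 * log((1-eps)/eps)`,
#' reweights instances by `exp(-alpha_t y_i h_t(x_i))` and renormalizes.
#' A round with `epsilon_t >= 0.5` is refit on a jittered bootstrap (at most
#' five seeded retries) and training stops early with the rounds accumulated
#' if none succeeds; a perfect round (`epsilon_t <= 1e-10`) gets a capped
#' alpha and also stops training. Labels are 0/1 at the interface, -1/+1
#' internally.
#'
#' @param X numeric feature matrix (or a fully numeric [tabular_dataset()];
#'   then `y` defaults to its target)
#' @param y binary 0/1 labels
#' @param cfg an [abdf_config()]
#' @return an object of class `abdf_model`: list of rounds
#'   `(learner, alpha, epsilon)` plus bookkeeping
#' @export
abdf_fit <- function(X, y = NULL, cfg = abdf_config()) {
  if (inherits(X, "tabular_dataset")) {
    if (is.null(y)) y <- X$target
    X <- feature_matrix(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n, all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  ym <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  rounds <- list()
  pool <- cfg$learner_pool
  eps_cap <- 1e-10

  with_local_seed(cfg$seed, {
    for (t in seq_len(cfg$n_estimators)) {
      spec <- pool[[((t - 1L) %% length(pool)) + 1L]]
      h <- fit_weak(spec, X, ym, w)
      pred <- predict_weak(h, X)
      eps <- sum(w * (pred != ym))
      retries <- 0
      while (eps >= 0.5 && retries < 5) {
        retries <- retries + 1
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        Xj <- X[idx, , drop = FALSE] +
          matrix(stats::rnorm(n * ncol(X), 0, 1e-6), n)
        h <- fit_weak(spec, Xj, ym[idx], rep(1 / n, n))
        pred <- predict_weak(h, X)
        eps <- sum(w * (pred != ym))
      }
      if (eps >= 0.5) break   # no learner beats chance; keep what we have
      if (eps <= eps_cap) {
        alpha <- learner_weight(eps_cap, cfg$learning_rate)
        rounds[[length(rounds) + 1]] <- list(learner = h, alpha = alpha,
                                             epsilon = eps)
        break                 # perfect learner: cap alpha and stop
      }
      alpha <- learner_weight(eps, cfg$learning_rate)
      rounds[[length(rounds) + 1]] <- list(learner = h, alpha = alpha,
                                           epsilon = eps)
      w <- w * exp(-alpha * ym * pred)
      w <- w / sum(w)
      stopifnot(abs(sum(w) - 1) < 1e-12)
    }
  })
  if (length(rounds) == 0) {
    stop("no weak learner beats chance on this data", call. = FALSE)
  }
  structure(list(rounds = rounds, n_features = ncol(X),
                 feature_names = colnames(X), config = cfg),
            class = "abdf_model")
}

#' @export
print.abdf_model <- function(x, ...) {
  eps <- vapply(x$rounds, `[[`, numeric(1), "epsilon")
  cat(sprintf("<abdf_model> %d round(s), weighted errors in [%.4f, %.4f]\n",
              length(x$rounds), min(eps), max(eps)))
  invisible(x)
}

#' Weighted-vote margin of the ensemble
#'
#' Returns `F(x) = sum_t alpha_t h_t(x)`; the predicted label is the sign of
#' `F` (zero mapped to +1).
#'
#' @param model a fitted [abdf_fit()] model
#' @param X numeric feature matrix or fully numeric [tabular_dataset()]
#' @return numeric vector of margins
#' @export
decision_function <- function(model, X) {
  stopifnot(inherits(model, "abdf_model"))
  if (length(model$rounds) == 0) stop("empty model", call. = FALSE)
  if (inherits(X, "tabular_dataset")) X <- feature_matrix(X)
  X <- as.matrix(X)
  F <- rep(0, nrow(X))
  for (r in model$rounds) F <- F + r$alpha * predict_weak(r$learner, X)
  F
}

#' Predict labels or probability-like scores
#'
#' @param object a fitted [abdf_fit()] model
#' @param X feature matrix or fully numeric [tabular_dataset()]
#' @param type `"class"` for 0/1 labels (sign of the margin, 0 mapped to +1)
#'   or `"score"` for the logistic squashing `1 / (1 + exp(-2 F))` used for
#'   ROC/AUC
#' @param ... unused
#' @return numeric vector
#' @export
predict.abdf_model <- function(object, X, type = c("class", "score"), ...) {
  type <- match.arg(type)
  F <- decision_function(object, X)
  if (type == "class") as.integer(F >= 0) else 1 / (1 + exp(-2 * F))
}

#' Training error of every prefix of the ensemble
#'
#' Error of `sign(sum_{t<=k} alpha_t h_t)` for `k = 1..T`; exposes the
#' boosting bound `prod_t 2 sqrt(eps_t (1 - eps_t))` for testing.
#'
#' @param model a fitted [abdf_fit()] model
#' @param X feature matrix or fully numeric [tabular_dataset()]
#' @param y binary 0/1 labels
#' @return numeric vector of length `length(model$rounds)`
#' @export
staged_training_error <- function(model, X, y) {
  if (inherits(X, "tabular_dataset")) {
    if (missing(y)) y <- X$target
    X <- feature_matrix(X)
  }
  X <- as.matrix(X)
  ym <- ifelse(y == 1, 1, -1)
  F <- rep(0, nrow(X))
  out <- numeric(length(model$rounds))
  for (k in seq_along(model$rounds)) {
    r <- model$rounds[[k]]
    F <- F + r$alpha * predict_weak(r$learner, X)
    pred <- ifelse(F >= 0, 1, -1)
    out[k] <- mean(pred != ym)
  }
  out
}

#' Serialize a stump/logistic ensemble to JSON
#'
#' @param model a fitted [abdf_fit()] model whose rounds are decision stumps
#' @param path output path
#' @return `path`, invisibly
#' @export
abdf_to_json <- function(model, path) {
  rounds <- lapply(model$rounds, function(r) {
    if (!inherits(r$learner, "stump")) {
      stop("JSON serialization supports decision-stump ensembles only",
           call. = FALSE)
    }
    list(kind = "decision_stump", feature = r$learner$feature,
         threshold = r$learner$threshold, polarity = r$learner$polarity,
         alpha = r$alpha, epsilon = r$epsilon)
  })
  jsonlite::write_json(list(n_features = model$n_features,
                            feature_names = model$feature_names,
                            rounds = rounds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a model written by [abdf_to_json()]
#' @param path JSON path
#' @return an `abdf_model`
#' @export
abdf_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rounds <- lapply(obj$rounds, function(r) {
    list(learner = structure(list(feature = r$feature, threshold = r$threshold,
                                  polarity = r$polarity), class = "stump"),
         alpha = r$alpha, epsilon = r$epsilon)
  })
  structure(list(rounds = rounds, n_features = obj$n_features,
                 feature_names = unlist(obj$feature_names), config = NULL),
            class = "abdf_model")
}
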