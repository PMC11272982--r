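#' Wrapper-fitness configuration for the subset search
#'
#' The swarm's objective is penalized cross-validated accuracy of a small,
#' fixed boosted-stump classifier: mean stratified k-fold validation accuracy
#' on the candidate subset minus `lambda * |subset| / d`. The fold assignment
#' is drawn once from the seed, so all subsets are compared on the same folds
#' (paired comparisons reduce evaluation noise). The internal classifier is
#' deliberately small — five stump rounds at learning rate 1 — to keep the
#' wrapper fast and its subset comparisons stable.
#'
#' @param folds number of stratified folds (default 3)
#' @param lambda subset-size penalty weight (default 0.01)
#' @param n_estimators boosting rounds of the internal classifier (default 5)
#' @param learning_rate learning rate of the internal classifier (default 1)
#' @param classifier `"abdf"` for the boosted stumps, `"majority"` for a
#'   constant majority-class baseline (useful in tests)
#' @param seed integer seed for the fold assignment
#' @return an object of class `fitness_config`
#' @export
fitness_config <- function(folds = 3, lambda = 0.01, n_estimators = 5,
                           learning_rate = 1.0,
                           classifier = c("abdf", "majority"), seed = 0) {
  classifier <- match.arg(classifier)
  stopifnot(folds >= 2, lambda >= 0)
  structure(list(folds = as.integer(folds), lambda = lambda,
                 n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate, classifier = classifier,
                 seed = as.integer(seed)),
            class = "fitness_config")
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin into folds.
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k) {
    stop("a class has fewer members than folds; cannot stratify", call. = FALSE)
  }
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      rows <- sample(which(y == cls))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

#' Penalized cross-validated fitness of a feature subset
#'
#' @param subset integer indices or character names of candidate features
#'   (non-empty)
#' @param ds a fully numeric, complete [tabular_dataset()] (training data)
#' @param cfg a [fitness_config()]
#' @return mean stratified k-fold validation accuracy minus
#'   `lambda * |subset| / d`
#' @export
subset_fitness <- function(subset, ds, cfg = fitness_config()) {
  stopifnot(length(subset) >= 1)
  if (is.numeric(subset)) subset <- feature_names(ds)[subset]
  d <- length(feature_names(ds))
  X <- feature_matrix(take_features(ds, subset))
  y <- ds$target
  fold <- stratified_folds(y, cfg$folds, cfg$seed)
  acc <- vapply(seq_len(cfg$folds), function(f) {
    tr <- fold != f
    if (cfg$classifier == "majority") {
      maj <- as.integer(mean(y[tr]) >= 0.5)
      return(mean(y[!tr] == maj))
    }
    model <- abdf_fit(X[tr, , drop = FALSE], y[tr],
                      abdf_config(n_estimators = cfg$n_estimators,
                                  learning_rate = cfg$learning_rate,
                                  seed = cfg$seed))
    mean(stats::predict(model, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc) - cfg$lambda * length(subset) / d
}

#' Two-tier feature selection: swarm subset search + ridge re-scoring
#'
#' Tier 1 runs the grasshopper swarm over `[0,1]^d` with the penalized
#' cross-validated accuracy of [subset_fitness()] as objective (positions
#' binarized at 0.5); evaluations are memoized per subset since the swarm
#' revisits subsets. Tier 2 refits the tier-1 subset with ridge regression and
#' prunes by coefficient magnitude ([l2_rescore()]). The tier-1 score reported
#' for each feature is the mean fitness of evaluated subsets containing it
#' minus the mean of those excluding it — a declared convention for ranking,
#' since the subset search itself only produces an incumbent.
#'
#' @param ds a fully numeric, complete [tabular_dataset()] (training data)
#' @param goa_cfg a [goa_config()]
#' @param fitness_cfg a [fitness_config()]
#' @param ridge_cfg a [ridge_config()]
#' @return list with `selected` (character vector of final features),
#'   `table` (`feature_score_table` with GOA and L2 tiers), `tier1_subset`,
#'   `best_fitness` and the swarm `trace`
#' @export
gol2_select <- function(ds, goa_cfg = goa_config(),
                        fitness_cfg = fitness_config(),
                        ridge_cfg = ridge_config()) {
  feats <- feature_names(ds)
  d <- length(feats)
  cache <- new.env(parent = emptyenv())
  log_member <- vector("list", 0)
  log_fit <- numeric(0)
  objective <- function(pos) {
    sel <- binarize_position(pos)
    key <- paste(sel, collapse = ",")
    if (is.null(cache[[key]])) {
      cache[[key]] <- subset_fitness(sel, ds, fitness_cfg)
      member <- logical(d)
      member[sel] <- TRUE
      log_member[[length(log_member) + 1]] <<- member
      log_fit[length(log_fit) + 1] <<- cache[[key]]
    }
    cache[[key]]
  }
  res <- goa_optimize(objective, d, goa_cfg)
  tier1 <- feats[binarize_position(res$best_position)]

  member <- do.call(rbind, log_member)
  goa_score <- vapply(seq_len(d), function(j) {
    with_j <- log_fit[member[, j]]
    without_j <- log_fit[!member[, j]]
    if (length(with_j) == 0 || length(without_j) == 0) return(0)
    mean(with_j) - mean(without_j)
  }, numeric(1))
  tab1 <- data.frame(feature = feats, tier = "GOA", score = goa_score,
                     selected = feats %in% tier1, stringsAsFactors = FALSE)
  tab1 <- tab1[order(-tab1$score), ]

  tab2 <- l2_rescore(tier1, ds, ridge_cfg)
  table <- rbind(tab1, as.data.frame(tab2))
  rownames(table) <- NULL
  class(table) <- c("feature_score_table", "data.frame")
  list(selected = tab2$feature[tab2$selected],
       table = table, tier1_subset = tier1,
       best_fitness = res$best_fitness, trace = res$trace)
}
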