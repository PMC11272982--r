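# Shared fixtures, all generated in code.

# Small correlated-feature binary classification problem used for the
# boosting-reference comparisons (continuous features, distinct values, so
# the best stump is unambiguous).
make_boost_fixture <- function(seed, n = 40, d = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  score <- X[, 1] + 0.8 * X[, 2] - 0.5 * X[, 3] + rnorm(n, 0, 0.8)
  y <- as.integer(score > median(score))
  list(X = X, y = y)
}

# Planted-subset recovery problem: 13 standard-normal features of which
# f01-f03 carry strong effects; balanced classes.
make_recovery_spec <- function(seed, n = 500) {
  synthetic_spec(
    n_samples = n, class_counts = c(n / 2, n / 2),
    schema = numeric_schema(13),
    informative_features = c("f01", "f02", "f03"),
    effect_sizes = c(f01 = 2.5, f02 = 2.0, f03 = 1.5),
    noise_sd = 0.3, seed = seed
  )
}

# All-numeric dataset for preprocessing tests.
make_numeric_dataset <- function(seed, n = 120, d = 4, informative = "f01",
                                 effect = 2, noise_sd = 1) {
  eff <- stats::setNames(rep(effect, length(informative)), informative)
  generate_dataset(synthetic_spec(
    n_samples = n, class_counts = c(floor(n / 2), ceiling(n / 2)),
    schema = numeric_schema(d), informative_features = informative,
    effect_sizes = eff, noise_sd = noise_sd, seed = seed
  ))
}

# Hand-built two-stump ensemble for vote-arithmetic tests.
make_manual_model <- function(alphas, thresholds, polarities, feature = 1L) {
  rounds <- Map(function(a, thr, pol) {
    list(learner = structure(list(feature = feature, threshold = thr,
                                  polarity = pol), class = "stump"),
         alpha = a, epsilon = 0.3)
  }, alphas, thresholds, polarities)
  structure(list(rounds = rounds, n_features = 1L, feature_names = "x",
                 config = NULL), class = "abdf_model")
}
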