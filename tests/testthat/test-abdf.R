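test_that("vote weights follow the half-log-odds of the weighted error", {
  expect_equal(learner_weight(0.5), 0)
  expect_equal(learner_weight(0.2), log(2), tolerance = 1e-12)
  expect_equal(learner_weight(0.2, learning_rate = 0.5), log(2) / 2,
               tolerance = 1e-12)
})

test_that("separable data is fit perfectly with an early stop", {
  X <- matrix(1:10, ncol = 1)
  y <- as.integer(1:10 > 5)
  m <- abdf_fit(X, y, abdf_config(n_estimators = 10))
  expect_equal(length(m$rounds), 1)            # perfect stump, early stop
  expect_lte(m$rounds[[1]]$epsilon, 1e-10)
  expect_equal(predict(m, X), y)
})

test_that("weights renormalize each round and misclassified weights grow", {
  f <- make_boost_fixture(1)
  m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 8))
  # recompute the weight trajectory independently from the stored rounds
  n <- length(f$y)
  ym <- ifelse(f$y == 1, 1, -1)
  w <- rep(1 / n, n)
  for (r in m$rounds) {
    pred <- ifelse(f$X[, r$learner$feature] > r$learner$threshold,
                   r$learner$polarity, -r$learner$polarity)
    eps <- sum(w * (pred != ym))
    expect_equal(eps, r$epsilon, tolerance = 1e-12)
    expect_gt(r$alpha, 0)
    expect_lt(r$epsilon, 0.5)
    w_new <- w * exp(-r$alpha * ym * pred)
    w_new <- w_new / sum(w_new)
    expect_equal(sum(w_new), 1, tolerance = 1e-12)
    miss <- pred != ym
    expect_true(all(w_new[miss] > w[miss] * exp(-r$alpha) /
                      sum(w * exp(-r$alpha * ym * pred)) - 1e-15))
    w <- w_new
  }
})

test_that("the decision function is the alpha-weighted stump vote", {
  m1 <- make_manual_model(alphas = 1, thresholds = 0, polarities = 1)
  X <- matrix(c(-2, 3), ncol = 1)
  expect_equal(decision_function(m1, X), c(-1, 1))

  # two disagreeing rounds: the 0.7 learner wins the vote
  m2 <- make_manual_model(alphas = c(0.7, 0.3), thresholds = c(0, 0),
                          polarities = c(1, -1))
  expect_equal(decision_function(m2, X), c(-0.4, 0.4))
  expect_equal(predict(m2, X), c(0L, 1L))

  # margins recomputed from stored rounds match to 1e-12
  f <- make_boost_fixture(2)
  m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 6))
  manual <- rowSums(vapply(m$rounds, function(r) {
    r$alpha * ifelse(f$X[, r$learner$feature] > r$learner$threshold,
                     r$learner$polarity, -r$learner$polarity)
  }, numeric(length(f$y))))
  expect_equal(decision_function(m, f$X), manual, tolerance = 1e-12)
})

test_that("staged errors respect the exponential boosting bound", {
  for (s in c(1, 2, 3)) {
    f <- make_boost_fixture(s)
    m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 12, learning_rate = 1))
    staged <- staged_training_error(m, f$X, f$y)
    eps <- vapply(m$rounds, `[[`, numeric(1), "epsilon")
    bound <- prod(2 * sqrt(eps * (1 - eps)))
    expect_lte(staged[length(staged)], bound)
    # the first prefix is just the first stump's training error
    pred1 <- ifelse(f$X[, m$rounds[[1]]$learner$feature] >
                      m$rounds[[1]]$learner$threshold,
                    m$rounds[[1]]$learner$polarity,
                    -m$rounds[[1]]$learner$polarity)
    expect_equal(staged[1], mean(pred1 != ifelse(f$y == 1, 1, -1)))
  }
})

test_that("the (epsilon, alpha) sequences match the boosting reference", {
  ref <- read.csv(test_path("ref_adaboost.csv"))
  pool <- list(weak_learner_spec("decision_stump", criterion = "gini"))
  for (fs in unique(ref$fixture)) {
    f <- make_boost_fixture(fs)
    for (lr in unique(ref$learning_rate)) {
      m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 15,
                                          learning_rate = lr,
                                          learner_pool = pool))
      sub <- ref[ref$fixture == fs & ref$learning_rate == lr, ]
      expect_equal(length(m$rounds), nrow(sub))
      expect_equal(vapply(m$rounds, `[[`, numeric(1), "epsilon"),
                   sub$epsilon, tolerance = 1e-9)
      expect_equal(vapply(m$rounds, `[[`, numeric(1), "alpha"),
                   sub$alpha, tolerance = 1e-9)
    }
  }
})

test_that("flipping all labels flips every prediction", {
  f <- make_boost_fixture(4)
  m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 7))
  m_flip <- abdf_fit(f$X, 1L - f$y, abdf_config(n_estimators = 7))
  expect_equal(predict(m_flip, f$X), 1L - predict(m, f$X))
})

test_that("data no stump can beat leaves no usable round", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1L, 1L, 0L, 0L)   # XOR: every stump errs on exactly half the weight
  expect_error(abdf_fit(X, y, abdf_config(n_estimators = 3)),
               "beats chance")
})

test_that("stump ensembles round-trip through JSON", {
  f <- make_boost_fixture(5)
  m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 5))
  path <- tempfile(fileext = ".json")
  abdf_to_json(m, path)
  back <- abdf_from_json(path)
  expect_equal(decision_function(back, f$X), decision_function(m, f$X),
               tolerance = 1e-12)
})

test_that("a heterogeneous learner pool cycles across rounds", {
  skip_if_not_installed("rpart")
  f <- make_boost_fixture(6)
  pool <- list(weak_learner_spec("decision_stump"),
               weak_learner_spec("logistic_unit"))
  m <- abdf_fit(f$X, f$y, abdf_config(n_estimators = 4, learner_pool = pool))
  kinds <- vapply(m$rounds, function(r) class(r$learner)[1], character(1))
  expect_equal(kinds[1:2], c("stump", "logistic_unit"))
})
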