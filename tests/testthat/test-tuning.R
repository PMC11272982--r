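make_parts <- function(seed = 1) {
  ds <- generate_dataset(synthetic_spec(
    n_samples = 150, class_counts = c(75, 75), schema = numeric_schema(3),
    informative_features = c("f01", "f02"),
    effect_sizes = c(f01 = 2, f02 = 1.5), noise_sd = 0.4, seed = seed))
  make_partitions(ds, seed = seed)
}

test_that("the ledger walks the grid row-major with trials numbered from 0", {
  p <- make_parts()
  grid <- hyper_grid(c(50, 100, 200), c(0.1, 0.5, 1.0))
  # mocked evaluator: value encodes the hyperparameters, argmax at (200, 1.0)
  mock <- function(ne, lr, train, validation) ne / 1000 + lr / 10
  r <- babysit(p$train, p$validation, p$test, grid, seed = 1,
               trial_fn = mock,
               final_fn = function(ne, lr, fit, test) {
                 list(model = NULL, metrics = list(accuracy = 1))
               })
  expect_equal(r$ledger$trial_no, 0:8)
  expect_equal(r$ledger$n_estimators, rep(c(50L, 100L, 200L), each = 3))
  expect_equal(r$ledger$learning_rate, rep(c(0.1, 0.5, 1.0), 3))
  expect_equal(r$ledger$accuracy,
               rep(c(50, 100, 200) / 1000, each = 3) + rep(c(0.1, 0.5, 1) / 10, 3))
  expect_equal(r$best_trial, 8L)
  expect_equal(r$best_hyperparameters,
               list(n_estimators = 200L, learning_rate = 1.0))
})

test_that("ties are broken by the lowest trial number", {
  p <- make_parts()
  r <- babysit(p$train, p$validation, p$test, hyper_grid(c(10, 20), c(0.5, 1)),
               trial_fn = function(ne, lr, tr, va) 0.7,
               final_fn = function(ne, lr, fit, test) {
                 list(model = NULL, metrics = list(accuracy = 0.7))
               })
  expect_equal(r$best_trial, 0L)
  expect_equal(r$best_hyperparameters$n_estimators, 10L)
})

test_that("the winner is refit on train + validation and tested exactly once", {
  p <- make_parts()
  n_final <- 0L
  fit_sizes <- integer(0)
  test_sizes <- integer(0)
  r <- babysit(p$train, p$validation, p$test, hyper_grid(c(5, 10), c(1)),
               trial_fn = function(ne, lr, tr, va) ne,
               final_fn = function(ne, lr, fit, test) {
                 n_final <<- n_final + 1L
                 fit_sizes <<- c(fit_sizes, n_samples(fit))
                 test_sizes <<- c(test_sizes, n_samples(test))
                 list(model = "m", metrics = list(accuracy = 0.9))
               })
  expect_equal(n_final, 1L)
  expect_equal(fit_sizes, n_samples(p$train) + n_samples(p$validation))
  expect_equal(test_sizes, n_samples(p$test))
  expect_equal(r$best_hyperparameters$n_estimators, 10L)
})

test_that("trial values never fall below the validation scores of the best", {
  p <- make_parts(2)
  r <- babysit(p$train, p$validation, p$test, hyper_grid(c(5, 15), c(0.5, 1)),
               metric = "accuracy", seed = 3)
  expect_true(all(r$ledger$accuracy <= r$ledger$accuracy[r$best_trial + 1]))
  expect_true(all(r$ledger$accuracy >= 0 & r$ledger$accuracy <= 1))
  expect_s3_class(r$final_model, "abdf_model")
})

test_that("a rerun with the same seed reproduces the ledger bit for bit", {
  p <- make_parts(3)
  grid <- hyper_grid(c(5, 10), c(0.5, 1))
  r1 <- babysit(p$train, p$validation, p$test, grid, seed = 11)
  r2 <- babysit(p$train, p$validation, p$test, grid, seed = 11)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$best_trial, r2$best_trial)
  expect_identical(unclass(r1$test_metrics), unclass(r2$test_metrics))
})

test_that("a single-cell grid still produces a complete result", {
  p <- make_parts(4)
  r <- babysit(p$train, p$validation, p$test, hyper_grid(5, 1), seed = 5)
  expect_equal(nrow(r$ledger), 1)
  expect_equal(r$best_trial, 0L)
  expect_s3_class(r$test_metrics, "metrics_report")
  path <- tempfile(fileext = ".csv")
  write_ledger(r, path)
  back <- read.csv(path)
  expect_equal(back$trial_no, r$ledger$trial_no)
  expect_equal(back$accuracy, r$ledger$accuracy)
})
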