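test_that("a hand-counted confusion matrix gives the textbook metrics", {
  # tp = 3, fp = 1, tn = 4, fn = 2
  y_true <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  cm <- confusion(y_true, y_pred)
  expect_equal(cm$tp, 3); expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 4); expect_equal(cm$fn, 2)
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-12)
})

test_that("F1 is the harmonic mean of precision and recall", {
  set.seed(1)
  for (rep in 1:10) {
    y_true <- rbinom(30, 1, 0.5)
    y_pred <- rbinom(30, 1, 0.5)
    m <- compute_metrics(confusion(y_true, y_pred))
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 / (1 / max(m$precision, 1e-300) +
                              1 / max(m$recall, 1e-300)),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero-denominator ratios are 0 and flagged, never an error", {
  m <- compute_metrics(confusion(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_setequal(attr(m, "undefined"), c("precision", "recall", "f1"))
  expect_equal(m$accuracy, 1)
})

test_that("perfect separation gives all metrics equal to one", {
  y <- c(0, 0, 1, 1)
  m <- compute_metrics(confusion(y, y), scores = c(0.1, 0.2, 0.8, 0.9),
                       y_true = y)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1", "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))
})

test_that("the trapezoidal AUC equals the Mann-Whitney statistic", {
  set.seed(2)
  for (rep in 1:10) {
    n <- 40
    y <- c(rep(0, 15), rep(1, 25))
    s <- rnorm(n)                       # continuous, ties impossible a.s.
    auc <- attr(roc_curve(y, s), "auc")
    # rank-based Mann-Whitney oracle: P(score_pos > score_neg)
    r <- rank(s)
    u <- sum(r[y == 1]) - 25 * 26 / 2
    expect_equal(auc, u / (25 * 15), tolerance = 1e-12)
  }
  # with ties, grouped sweep still matches the tie-corrected statistic
  y <- c(0, 0, 1, 1, 0, 1)
  s <- c(1, 2, 2, 3, 3, 3)
  r <- rank(s)
  u <- sum(r[y == 1]) - 3 * 4 / 2
  expect_equal(attr(roc_curve(y, s), "auc"), u / 9, tolerance = 1e-12)
})

test_that("AUC is invariant to observation order and flips under negation", {
  set.seed(3)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(50)
  a <- attr(roc_curve(y, s), "auc")
  perm <- sample(50)
  expect_equal(attr(roc_curve(y[perm], s[perm]), "auc"), a, tolerance = 1e-12)
  expect_equal(attr(roc_curve(y, -s), "auc"), 1 - a, tolerance = 1e-12)
})

test_that("label-independent scores give an AUC of exactly one half", {
  y <- c(0, 1, 0, 1, 1, 0)
  expect_equal(attr(roc_curve(y, rep(0.3, 6)), "auc"), 0.5)
})

test_that("the ROC curve is a monotone path from (0,0) to (1,1)", {
  set.seed(4)
  y <- rbinom(30, 1, 0.4); y[1:2] <- c(0, 1)
  roc <- roc_curve(y, rnorm(30))
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_error(roc_curve(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("reports round-trip through the CSV/JSON writer", {
  y <- c(0, 0, 1, 1)
  m <- compute_metrics(confusion(y, c(0, 1, 1, 1)), scores = c(1, 2, 3, 4),
                       y_true = y)
  path <- file.path(tempdir(), "report.csv")
  write_report(list(abdf = m, baseline = m), path)
  csv <- read.csv(path)
  expect_equal(csv$model, c("abdf", "baseline"))
  expect_equal(names(csv),
               c("model", "accuracy", "precision", "recall", "f1", "auc"))
  expect_equal(csv$accuracy, c(0.75, 0.75))
  js <- jsonlite::read_json(sub("csv$", "json", path), simplifyVector = TRUE)
  expect_equal(js$f1, csv$f1, tolerance = 1e-12)
})
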