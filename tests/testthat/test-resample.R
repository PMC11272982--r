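test_that("imbalance ratio is minority over majority", {
  r <- imbalance_report(c(rep(0, 410), rep(1, 508)))
  expect_equal(round(r$ratio, 4), 0.8071)
  expect_true(r$triggered)

  bal <- imbalance_report(c(rep(0, 500), rep(1, 500)), threshold = 0.99)
  expect_equal(bal$ratio, 1.0)
  expect_false(bal$triggered)

  r2 <- imbalance_report(c(rep(0, 25), rep(1, 100)))
  expect_equal(r2$ratio, 0.25)
})

test_that("ratio times the majority count recovers the minority count", {
  for (counts in list(c(410, 508), c(3, 997), c(123, 877))) {
    r <- imbalance_report(c(rep(0, counts[1]), rep(1, counts[2])))
    expect_equal(r$ratio * r$count_majority, r$count_minority,
                 tolerance = 1e-12)
  }
})

test_that("a single-class target is rejected", {
  expect_error(imbalance_report(rep(1, 10)), "single class")
})

test_that("SMOTE balances 410/508 to 508/508 and keeps originals verbatim", {
  spec <- synthetic_spec(n_samples = 918, class_counts = c(410, 508),
                         schema = numeric_schema(5),
                         informative_features = "f01",
                         effect_sizes = c(f01 = 1.5), seed = 42)
  ds <- generate_dataset(spec)
  out <- smote_resample(ds, smote_config(seed = 1))
  expect_equal(sum(out$target == 0), 508)
  expect_equal(sum(out$target == 1), 508)
  n <- n_samples(ds)
  expect_identical(out$data[seq_len(n), ], ds$data)
  expect_identical(out$target[seq_len(n)], ds$target)
  # removing the synthetic rows recovers the input exactly
  expect_identical(take_rows(out, seq_len(n))$data, ds$data)
})

test_that("balanced input is returned unchanged and reruns are deterministic", {
  ds <- make_numeric_dataset(5, n = 40)
  expect_identical(smote_resample(ds), ds)

  spec <- synthetic_spec(n_samples = 60, class_counts = c(20, 40),
                         schema = numeric_schema(3),
                         informative_features = "f01",
                         effect_sizes = c(f01 = 1), seed = 2)
  imb <- generate_dataset(spec)
  expect_identical(smote_resample(imb, smote_config(seed = 7)),
                   smote_resample(imb, smote_config(seed = 7)))
})

test_that("every synthetic row is a convex combination of its parent and a k-NN", {
  spec <- synthetic_spec(n_samples = 90, class_counts = c(30, 60),
                         schema = numeric_schema(4),
                         informative_features = "f01",
                         effect_sizes = c(f01 = 1), seed = 3)
  ds <- generate_dataset(spec)
  k <- 5
  out <- smote_resample(ds, smote_config(k_neighbors = k, seed = 4))
  lineage <- attr(out, "smote_lineage")
  X <- as.matrix(ds$data)
  minority_rows <- which(ds$target == 0)
  n <- n_samples(ds)
  for (i in seq_len(nrow(lineage))) {
    s <- as.numeric(out$data[n + i, ])
    p <- X[lineage$parent[i], ]
    q <- X[lineage$neighbor[i], ]
    u <- lineage$u[i]
    expect_equal(s, unname(p + u * (q - p)), tolerance = 1e-12)
    expect_true(u >= 0 && u <= 1)
    # the chosen neighbor is among the k nearest minority rows by a
    # brute-force double-loop distance computation
    others <- setdiff(minority_rows, lineage$parent[i])
    dists <- vapply(others, function(j) sqrt(sum((X[j, ] - p)^2)), numeric(1))
    knn <- others[order(dists)[seq_len(k)]]
    d_chosen <- sqrt(sum((q - p)^2))
    expect_lte(d_chosen, max(dists[match(knn, others)]) + 1e-12)
  }
})

test_that("small minorities reduce k with a warning; a singleton is an error", {
  spec <- synthetic_spec(n_samples = 24, class_counts = c(4, 20),
                         schema = numeric_schema(3),
                         informative_features = "f01",
                         effect_sizes = c(f01 = 1), seed = 6)
  ds <- generate_dataset(spec)
  expect_warning(out <- smote_resample(ds, smote_config(k_neighbors = 5)),
                 "reducing k")
  expect_equal(sum(out$target == 0), 20)

  one <- take_rows(ds, c(which(ds$target == 0)[1], which(ds$target == 1)))
  expect_error(smote_resample(one), "single row")
})
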