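#' Stratified train/test split
#'
#' Assigns `round(train_fraction * n)` rows to the training partition,
#' stratified by the binary target (per-class counts by largest remainder so
#' the overall count is exact). Partitions are disjoint and exhaustive.
#'
#' @param ds a [tabular_dataset()]
#' @param train_fraction fraction in (0, 1); default 0.7
#' @param seed integer seed
#' @return list with `train` and `test` ([tabular_dataset()]s) and the
#'   corresponding row indices `train_idx`, `test_idx`
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 0) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  y <- ds$target
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop("each class needs at least 2 members to split", call. = FALSE)
  }
  n <- length(y)
  n_train <- round(train_fraction * n)
  # largest-remainder apportionment of the train quota across classes
  quota <- stats::setNames(train_fraction * as.numeric(counts), names(counts))
  base <- floor(quota)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    fewer <- order(quota - base)[seq_len(-rem)]
    base[fewer] <- base[fewer] - 1
  }
  with_local_seed(seed, {
    train_idx <- integer(0)
    for (cls in c(0, 1)) {
      rows <- which(y == cls)
      take <- base[as.character(cls)]
      train_idx <- c(train_idx, sample(rows, take))
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n), train_idx)
    list(train = take_rows(ds, train_idx), test = take_rows(ds, test_idx),
         train_idx = train_idx, test_idx = test_idx)
  })
}

#' Stratified three-way train/validation/test partition
#'
#' The default carves the validation set out of the 70% training share
#' (80/20), leaving an untouched 30% test set: fractions
#' `(0.7 * 0.8, 0.7 * 0.2, 0.3)`.
#'
#' @param ds a [tabular_dataset()]
#' @param fractions length-3 vector summing to 1
#' @param seed integer seed
#' @return list with `train`, `validation`, `test` ([tabular_dataset()]s)
#' @export
make_partitions <- function(ds, fractions = c(0.7 * 0.8, 0.7 * 0.2, 0.3),
                            seed = 0) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  s1 <- split_dataset(ds, fractions[1] + fractions[2], seed = seed)
  s2 <- split_dataset(s1$train, fractions[1] / (fractions[1] + fractions[2]),
                      seed = seed + 1L)
  list(train = s2$train, validation = s2$test, test = s1$test)
}
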