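test_that("one-vs-rest confusion counts enumerate correctly", {
  cc <- confusion_counts(c(1, 0, 1, 1), c(1, 1, 0, 1), levels = c("0", "1"))
  row1 <- cc$per_class[cc$per_class$class == "1", ]
  expect_equal(unlist(row1[c("tp", "fn", "fp", "tn")]),
               c(tp = 2, fn = 1, fp = 1, tn = 0))
  # all correct: no false positives or negatives
  cc2 <- confusion_counts(c("a", "b", "a"), c("a", "b", "a"))
  expect_true(all(cc2$per_class$fp == 0) && all(cc2$per_class$fn == 0))
  # permuting samples leaves counts unchanged
  set.seed(1)
  y <- sample(letters[1:3], 60, replace = TRUE)
  p <- sample(letters[1:3], 60, replace = TRUE)
  perm <- sample(60)
  expect_equal(confusion_counts(y, p, letters[1:3])$per_class,
               confusion_counts(y[perm], p[perm], letters[1:3])$per_class)
  # class-wise counts always sum to n
  cc3 <- confusion_counts(y, p, letters[1:3])
  expect_true(all(rowSums(cc3$per_class[, c("tp", "tn", "fp", "fn")]) == 60))
  expect_error(confusion_counts(c("a", "x"), c("a", "a"), levels = "a"),
               "outside")
})

test_that("metric formulas match worked arithmetic and edge rules", {
  m <- classification_metrics(list(tp = 50, tn = 40, fp = 5, fn = 5))
  expect_equal(unname(m["accuracy"]), 0.90)
  expect_equal(unname(m["sensitivity"]), 50 / 55, tolerance = 1e-12)
  expect_equal(unname(m["precision"]), 50 / 55, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 50 / 55, tolerance = 1e-12)
  expect_equal(round(unname(m["sensitivity"]), 4), 0.9091)
  # perfect classifier
  expect_equal(unname(classification_metrics(
    list(tp = 10, tn = 10, fp = 0, fn = 0))),
    c(1, 1, 1, 1))
  # tp = 0 with fn > 0: sensitivity and f1 are defined zero (with warnings)
  w <- testthat::capture_warnings(
    m0 <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 5)))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(unname(m0[c("sensitivity", "f1")]), c(0, 0))
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "undefined")
})

test_that("metrics agree with independent recomputation on fuzzed counts", {
  set.seed(42)
  for (i in seq_len(1000)) {
    cnt <- as.list(stats::setNames(sample(0:100, 4, replace = TRUE),
                                   c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cnt)) == 0) next
    m <- suppressWarnings(classification_metrics(cnt))
    with(cnt, {
      expect_equal(unname(m["accuracy"]), (tp + tn) / (tp + tn + fp + fn))
      sens <- if (tp + fn > 0) tp / (tp + fn) else 0
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      expect_equal(unname(m["sensitivity"]), sens)
      expect_equal(unname(m["precision"]), prec)
      f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
      expect_equal(unname(m["f1"]), f1)
    })
  }
})

test_that("macro averaging is the unweighted class mean", {
  r <- c(accuracy = 0.9, sensitivity = 0.8, precision = 0.7, f1 = 0.6)
  expect_equal(macro_average(list(r, r)), r)
  expect_equal(macro_average(list(r)), r)
  a <- c(accuracy = 1, sensitivity = 1, precision = 1, f1 = 1)
  b <- c(accuracy = 0, sensitivity = 0, precision = 0, f1 = 0)
  expect_equal(unname(macro_average(list(a, b))["f1"]), 0.5)
  # micro (pooled) accuracy equals plain accuracy
  set.seed(2)
  y <- sample(letters[1:4], 80, replace = TRUE)
  p <- sample(letters[1:4], 80, replace = TRUE)
  cc <- confusion_counts(y, p, letters[1:4])
  pooled <- classification_metrics(cc$pooled)
  k <- 4
  plain <- mean(y == p)
  # pooled OVR accuracy relates to plain accuracy as (k - 2 + 2 acc) / k
  expect_equal(unname(pooled["accuracy"]), (k - 2 + 2 * plain) / k)
})

test_that("holdout split is stratified, disjoint and exhaustive", {
  y <- factor(rep(c("a", "b"), times = c(60, 40)))
  sp <- holdout_split(y, 0.8, seed = 3)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  # class proportions preserved within one sample
  expect_equal(sum(y[sp$train] == "a"), 48)
  expect_equal(sum(y[sp$train] == "b"), 32)
  expect_error(holdout_split(y, 1.2), "train_fraction")
})

test_that("fold assignment partitions evenly with stratification", {
  y <- factor(sample(rep(c("a", "b", "c"), times = c(137, 150, 150))))
  fa <- fold_assignment(y, folds = 10, seed = 7)
  expect_length(fa, length(y))
  sizes <- table(fa)
  expect_lte(max(sizes) - min(sizes), 1L)
  # per class, fold counts also differ by at most one
  for (k in levels(y)) {
    s <- table(factor(fa[y == k], levels = 1:10))
    expect_lte(max(s) - min(s), 1L)
  }
  expect_identical(fa, fold_assignment(y, folds = 10, seed = 7))
  expect_warning(fold_assignment(factor(rep(c("a", "b"), c(5, 50))),
                                 folds = 10, seed = 1),
                 "fewer than")
})

test_that("ten-fold cross-validation partitions, reports and reproduces", {
  ft <- small_dataset(seed = 55)
  cfg <- quick_config(seed = 2)
  rep1 <- ten_fold_cv(cfg, ft, seed = 9)
  expect_equal(nrow(rep1), 11L)
  expect_equal(rep1$fold, c(as.character(1:10), "mean"))
  # every sample in exactly one test fold
  assign <- attr(rep1, "assignment")
  expect_length(assign, nrow(ft$X))
  expect_true(all(assign %in% 1:10))
  # mean row equals the column means of the fold rows
  body <- as.data.frame(rep1)[1:10, -1]
  expect_equal(unlist(as.data.frame(rep1)[11, -1]),
               colMeans(body), tolerance = 1e-12)
  # metrics live on [0, 1]
  expect_true(all(body >= 0 & body <= 1))
  # fixed seed reproduces the identical report
  rep2 <- ten_fold_cv(cfg, ft, seed = 9)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  # CSV export renders percentages
  p <- tempfile(fileext = ".csv")
  write_fold_report(rep1, p)
  out <- read.csv(p)
  expect_equal(out$accuracy[1:10], round(100 * body$accuracy, 2))
})

test_that("comparison report reproduces the published difference bounds", {
  ours <- c(accuracy = 98.59, sensitivity = 97.82, precision = 98.69,
            f1 = 98.48)
  rep <- comparison_report(ours)
  s <- attr(rep, "summary")
  expect_equal(s["max", "accuracy"], 9.73)   # vs AdaBoost 88.86
  expect_equal(s["min", "accuracy"], 2.29)   # vs CNN-LSTM 96.30
  expect_equal(s["min", "f1"], 0.18)         # vs Gradient-Boost Tree 98.30
  expect_equal(s["max", "f1"], 20.63)        # vs Decision Tree 77.85
  expect_equal(s["min", "sensitivity"], 1.82)
  expect_equal(s["max", "sensitivity"], 19.86)
  expect_equal(s["min", "precision"], 3.19)
  expect_equal(s["max", "precision"], 20.74)
  # identical competitor rows give zero differences
  same <- data.frame(model = "self", accuracy = 98.59, sensitivity = 97.82,
                     precision = 98.69, f1 = 98.48)
  rep0 <- comparison_report(ours, same)
  expect_equal(unlist(as.data.frame(rep0)[1, -1]),
               c(accuracy = 0, sensitivity = 0, precision = 0, f1 = 0))
  # NA competitor entries stay NA and are skipped in the summary
  expect_true(is.na(as.data.frame(rep)[7, "accuracy"]))
})
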