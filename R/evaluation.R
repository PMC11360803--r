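#' One-vs-rest confusion counts
#'
#' For every class, samples of that class are the positives and all others
#' the negatives; pooled (micro) counts are the sums over classes. For each
#' class, tp + tn + fp + fn equals the number of samples.
#'
#' @param true,predicted equal-length label vectors (factor or character).
#' @param levels class labels; defaults to the union of observed labels in
#'   order of appearance in \code{true}.
#' @return object of class \code{"confusion_counts"}: \code{per_class}
#'   data frame (class, tp, tn, fp, fn), \code{pooled} list, \code{n}.
#' @export
confusion_counts <- function(true, predicted, levels = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("label vectors must have equal length")
  if (is.null(levels)) levels <- unique(c(true, predicted))
  bad <- setdiff(unique(c(true, predicted)), levels)
  if (length(bad))
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  per <- do.call(rbind, lapply(levels, function(k) {
    tp <- sum(true == k & predicted == k)
    fn <- sum(true == k & predicted != k)
    fp <- sum(true != k & predicted == k)
    tn <- sum(true != k & predicted != k)
    data.frame(class = k, tp = tp, tn = tn, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  }))
  pooled <- list(tp = sum(per$tp), tn = sum(per$tn),
                 fp = sum(per$fp), fn = sum(per$fn))
  structure(list(per_class = per, pooled = pooled, n = length(true),
                 levels = levels),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy \code{(TP+TN)/(TP+TN+FP+FN)}, sensitivity (recall)
#' \code{TP/(TP+FN)}, precision \code{TP/(TP+FP)} and F1, the harmonic mean
#' of precision and recall. A zero denominator yields 0 with a warning so
#' that fold averages stay defined; all-zero counts are an error.
#'
#' @param counts a list or one-row data frame with tp, tn, fp, fn.
#' @return named numeric vector (accuracy, sensitivity, precision, f1) on
#'   the [0, 1] scale.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be non-negative")
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero; metrics undefined")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  acc <- safe(tp + tn, tp + tn + fp + fn, "accuracy")
  sens <- safe(tp, tp + fn, "sensitivity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (prec + sens == 0) {
    warning("zero denominator for f1; reporting 0")
    0
  } else 2 * prec * sens / (prec + sens)
  c(accuracy = acc, sensitivity = sens, precision = prec, f1 = f1)
}

#' Macro-average per-class metric reports
#'
#' Unweighted mean of each metric over classes: the default multi-class
#' summary, robust to the class imbalance a BACKGROUND class introduces.
#'
#' @param reports list of [classification_metrics()] vectors, or a
#'   [confusion_counts()] object (metrics computed per class).
#' @return named numeric vector (accuracy, sensitivity, precision, f1).
#' @export
macro_average <- function(reports) {
  if (inherits(reports, "confusion_counts"))
    reports <- lapply(seq_len(nrow(reports$per_class)), function(i)
      classification_metrics(reports$per_class[i, ]))
  if (!length(reports)) stop("need at least one class report")
  colMeans(do.call(rbind, reports))
}

#' Macro metrics of a prediction vector
#'
#' Convenience wrapper: one-vs-rest confusion per class, per-class metrics,
#' macro average. Zero-denominator warnings from empty classes are
#' suppressed here (they are expected when a fold lacks a class).
#'
#' @inheritParams confusion_counts
#' @return named numeric vector (accuracy, sensitivity, precision, f1).
#' @export
evaluate_predictions <- function(true, predicted, levels = NULL) {
  cc <- confusion_counts(true, predicted, levels)
  suppressWarnings(macro_average(cc))
}

#' Stratified holdout split
#'
#' Splits samples into train/test index sets, preserving class proportions
#' to within one sample per class (indices within each class are shuffled,
#' the first \code{floor(fraction * n_class)} go to train).
#'
#' @param table a [feature_table()] with labels, or a label vector.
#' @param train_fraction fraction in (0, 1) assigned to training.
#' @param seed integer seed for the shuffle.
#' @return list with integer index vectors \code{train} and \code{test};
#'   disjoint and exhaustive.
#' @export
holdout_split <- function(table, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  y <- if (inherits(table, "feature_table")) table$y else table
  if (is.null(y)) stop("holdout split needs labels")
  set.seed(seed)
  train <- integer(0)
  for (k in unique(as.character(y))) {
    idx <- sample(which(as.character(y) == k))
    n_tr <- floor(train_fraction * length(idx))
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals its members round-robin over folds, so fold
#' sizes differ by at most one and class proportions are preserved. Classes
#' with fewer members than folds trigger a warning and an unstratified
#' assignment.
#'
#' @param y label vector.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..folds), one per sample.
#' @export
fold_assignment <- function(y, folds = 10L, seed = 1L) {
  set.seed(seed)
  n <- length(y)
  assign <- integer(n)
  counts <- table(as.character(y))
  if (any(counts < folds)) {
    warning("class(es) with fewer than ", folds,
            " members; falling back to unstratified folds")
    assign <- sample(rep_len(seq_len(folds), n))
    return(assign)
  }
  offset <- 0L
  for (k in names(counts)) {
    idx <- sample(which(as.character(y) == k))
    # rotate the starting fold between classes so fold sizes balance
    assign[idx] <- (offset + seq_along(idx) - 1L) %% folds + 1L
    offset <- offset + length(idx)
  }
  assign
}

#' Ten-fold cross-validated evaluation of the SHO-trained network
#'
#' For each fold: the z-score model is fitted on the nine training folds
#' only, applied to both sides, the network is trained by Sea Horse
#' Optimization on the training folds and evaluated on the held-out fold
#' with macro-averaged accuracy, sensitivity, precision and F1. The report
#' carries one row per fold plus a mean row (the arithmetic mean of the
#' fold rows).
#'
#' @param config a [training_config()].
#' @param table a labeled [feature_table()].
#' @param seed integer seed controlling fold assignment and per-fold
#'   training seeds.
#' @param folds number of folds (default 10).
#' @return object of class \code{"fold_report"}: data frame with columns
#'   fold, accuracy, sensitivity, precision, f1 (proportions in [0, 1]);
#'   attribute \code{assignment} holds the fold ids.
#' @export
ten_fold_cv <- function(config, table, seed = 1L, folds = 10L) {
  if (is.null(table$y)) stop("cross-validation needs a labeled table")
  assign <- fold_assignment(table$y, folds = folds, seed = seed)
  lev <- levels(droplevels(table$y))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    zs <- fit_zscore(table$X[tr, , drop = FALSE])
    xtr <- apply_zscore(zs, table$X[tr, , drop = FALSE])
    xte <- apply_zscore(zs, table$X[te, , drop = FALSE])
    cfg <- config
    cfg$seed <- (config$seed + 1000L * f) %% .Machine$integer.max
    model <- shodnn_train(cfg, xtr, droplevels(table$y[tr]))
    pred <- predict(model, xte)
    m <- evaluate_predictions(as.character(table$y[te]), pred, levels = lev)
    rows[[f]] <- data.frame(fold = as.character(f), t(m))
  }
  df <- do.call(rbind, rows)
  mean_row <- data.frame(fold = "mean", t(colMeans(df[, -1])))
  out <- rbind(df, mean_row)
  rownames(out) <- NULL
  structure(out, class = c("fold_report", "data.frame"),
            assignment = assign, seed = seed)
}

#' @export
print.fold_report <- function(x, ...) {
  cat("cross-validated performance (%):\n")
  shown <- x
  shown[, -1] <- round(100 * shown[, -1], 2)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Write a fold report as CSV (percentages, two decimals)
#'
#' @param report a [ten_fold_cv()] report.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fold_report <- function(report, path) {
  out <- as.data.frame(report)
  out[, -1] <- round(100 * out[, -1], 2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Published performance of comparison models
#'
#' Reported accuracy, sensitivity, precision and F1 (percent) of nine
#' gesture- or adherence-recognition models from the prior literature, as
#' consumed by [comparison_report()]. Missing entries are NA as published.
#'
#' @return data frame with columns model, accuracy, sensitivity, precision,
#'   f1.
#' @export
competitor_metrics <- function() {
  data.frame(
    model = c("Random Forest", "AdaBoost", "DNN", "CNN", "CNN-LSTM",
              "Decision Tree", "Bayesian Network", "Gradient-Boost Tree",
              "MLP"),
    accuracy = c(91.40, 88.86, 92.10, 95.70, 96.30, 91.18, NA, NA, 95.94),
    sensitivity = c(87.70, 82.20, 90.40, 96.00, 95.50, 77.96, 90.00, NA,
                    89.84),
    precision = c(95.50, 95.20, 94.30, 94.00, 94.00, 77.95, 90.62, NA,
                  89.75),
    f1 = c(91.40, 88.20, 92.30, 92.50, 92.50, 77.85, NA, 98.30, 89.77),
    stringsAsFactors = FALSE
  )
}

#' Difference table against published competitor models
#'
#' Per metric, the difference \code{ours - competitor} for every competitor
#' row (NA entries stay NA), plus the min/max difference over the non-NA
#' rows.
#'
#' @param ours named vector with accuracy, sensitivity, precision, f1 on the
#'   percent scale.
#' @param competitors competitor table (default [competitor_metrics()]).
#' @return object of class \code{"comparison_report"}: the difference data
#'   frame with a \code{summary} attribute (min/max per metric).
#' @export
comparison_report <- function(ours, competitors = competitor_metrics()) {
  metrics <- c("accuracy", "sensitivity", "precision", "f1")
  if (!all(metrics %in% names(ours)))
    stop("`ours` must carry accuracy, sensitivity, precision and f1")
  diffs <- competitors
  for (m in metrics) diffs[[m]] <- ours[[m]] - competitors[[m]]
  summ <- sapply(metrics, function(m) {
    v <- diffs[[m]][!is.na(diffs[[m]])]
    c(min = min(v), max = max(v))
  })
  structure(diffs, class = c("comparison_report", "data.frame"),
            ours = ours[metrics], summary = summ)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("difference (ours - competitor), percentage points:\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  cat("\nrange over models:\n")
  print(attr(x, "summary"))
  invisible(x)
}
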