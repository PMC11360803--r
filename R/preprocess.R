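#' Fit a z-score normalization model
#'
#' Per-feature standardization \code{(value - mean) / SD}. The SD is the
#' population form (divisor \code{n}), which keeps a single-row table
#' defined; values below the column mean map to negative numbers, values
#' above to positive, values exactly at the mean to 0.
#'
#' Fit the model on training data only and apply it to held-out data with
#' [apply_zscore()] so no test-set statistics leak into training.
#'
#' @param x a [feature_table()] or a numeric matrix / data frame.
#' @return an object of class \code{"zscore_model"} with \code{means},
#'   \code{sds} and \code{feature_names}.
#' @export
fit_zscore <- function(x) {
  X <- if (inherits(x, "feature_table")) x$X else as.matrix(x)
  if (nrow(X) < 1L) stop("cannot fit a z-score model on an empty table")
  means <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2L, means)^2))
  structure(list(means = means, sds = sds, feature_names = colnames(X)),
            class = "zscore_model")
}

#' Apply a fitted z-score model
#'
#' Columns whose fitted SD is 0 (constant in the training data) transform to
#' 0 everywhere rather than dividing by zero.
#'
#' @param model a [fit_zscore()] model.
#' @param x a [feature_table()] or numeric matrix with matching feature
#'   names.
#' @return object of the same type as \code{x}, transformed.
#' @export
apply_zscore <- function(model, x) {
  is_ft <- inherits(x, "feature_table")
  X <- if (is_ft) x$X else as.matrix(x)
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names))
    stop("feature names do not match the fitted z-score model")
  if (ncol(X) != length(model$means))
    stop("feature count does not match the fitted z-score model")
  Z <- sweep(X, 2L, model$means)
  nz <- model$sds > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, model$sds[nz], "/")
  Z[, !nz] <- 0
  if (is_ft) feature_table(Z, x$y) else Z
}

#' @export
print.zscore_model <- function(x, ...) {
  cat("z-score model over", length(x$means), "features\n")
  invisible(x)
}

#' Serialize a z-score model to a plain-text file
#'
#' One tab-separated line per feature: name, mean, SD (full precision).
#'
#' @param model a [fit_zscore()] model.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_zscore_model <- function(model, path) {
  nm <- model$feature_names
  if (is.null(nm)) nm <- paste0("f", seq_along(model$means))
  writeLines(sprintf("%s\t%.17g\t%.17g", nm, model$means, model$sds), path)
  invisible(path)
}

#' Read a serialized z-score model
#'
#' @param path file written by [write_zscore_model()].
#' @return a \code{"zscore_model"}.
#' @export
read_zscore_model <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("name", "mean", "sd"),
                          colClasses = c("character", "numeric", "numeric"))
  structure(list(means = stats::setNames(df$mean, df$name),
                 sds = stats::setNames(df$sd, df$name),
                 feature_names = df$name),
            class = "zscore_model")
}
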