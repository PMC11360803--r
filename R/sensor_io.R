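#' Gesture vocabulary
#'
#' The five steps of the monitored pill-taking sequence plus a BACKGROUND
#' class for everything between gestures: opening the bottle, tipping a pill
#' into the free hand, tossing the pill to the mouth, drinking water, closing
#' the bottle.
#'
#' @return character vector of the six class labels, gestures first.
#' @export
gesture_labels <- function() {
  c("OPEN_BOTTLE", "TIP_PILL", "TOSS_PILL", "DRINK_WATER", "CLOSE_BOTTLE",
    "BACKGROUND")
}

#' Read a per-sensor CSV stream
#'
#' Expected dialect: one file per sensor stream with a mandatory header and
#' columns \code{epoch_ms} (integer milliseconds), \code{elapsed_s},
#' \code{x}, \code{y}, \code{z}. Rows with unparseable values are dropped,
#' counted and reported in the \code{"malformed"} attribute; timestamps must
#' be strictly increasing.
#'
#' @param path CSV file path.
#' @param sensor_kind label attached to the stream, e.g.
#'   \code{"accelerometer"} or \code{"gyroscope"} (units g and deg/s).
#' @return data frame of samples in timestamp order, with attributes
#'   \code{sensor_kind} and \code{malformed} (dropped-row count).
#' @export
read_sensor_csv <- function(path, sensor_kind = "accelerometer") {
  if (!file.exists(path)) stop("sensor file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("epoch_ms", "elapsed_s", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sensor CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  for (cc in required) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  ok <- stats::complete.cases(df)
  malformed <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) > 1L) {
    dd <- diff(df$epoch_ms)
    if (any(dd <= 0)) {
      line <- which(dd <= 0)[1] + 1L
      stop("timestamps are not strictly increasing; first violation at ",
           "data row ", line)
    }
  }
  rownames(df) <- NULL
  attr(df, "sensor_kind") <- sensor_kind
  attr(df, "malformed") <- malformed
  df
}

#' Write a per-sensor CSV stream
#'
#' Inverse of [read_sensor_csv()]; values are written at full precision so a
#' write/read round trip is exact.
#'
#' @param samples data frame with columns epoch_ms, elapsed_s, x, y, z.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sensor_csv <- function(samples, path) {
  required <- c("epoch_ms", "elapsed_s", "x", "y", "z")
  if (!all(required %in% names(samples)))
    stop("samples must have columns ", paste(required, collapse = ", "))
  df <- as.data.frame(samples)[required]
  lines <- c(paste(required, collapse = ","),
             sprintf("%.0f,%.17g,%.17g,%.17g,%.17g",
                     df$epoch_ms, df$elapsed_s, df$x, df$y, df$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write gesture annotations
#'
#' Annotations are a side CSV with columns \code{start_ms}, \code{end_ms},
#' \code{label}; labels come from [gesture_labels()].
#'
#' @param path CSV path.
#' @return data frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("start_ms", "end_ms", "label")
  if (!all(required %in% names(df)))
    stop("annotation CSV must have columns ", paste(required, collapse = ", "))
  bad <- setdiff(unique(df$label), gesture_labels())
  if (length(bad))
    stop("unknown gesture label(s): ", paste(bad, collapse = ", "))
  df[required]
}

#' @rdname read_annotations
#' @param annotations data frame with start_ms, end_ms, label.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[c("start_ms", "end_ms", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Bundle aligned sensor streams into a recording
#'
#' The accelerometer and gyroscope streams must be sampled on the same
#' timestamps (the wearable exports both at the device rate); an optional
#' magnetometer stream may be attached. Annotation intervals must be
#' non-overlapping and lie within the recording extent.
#'
#' @param accelerometer,gyroscope sample data frames (epoch_ms, elapsed_s,
#'   x, y, z), equal length and identical timestamps.
#' @param nominal_rate_hz nominal sampling rate; must be in (0, 400], the
#'   device cap.
#' @param subject_id identifier string.
#' @param annotations optional annotation data frame.
#' @param magnetometer optional third stream.
#' @return an object of class \code{"sensor_recording"}.
#' @export
sensor_recording <- function(accelerometer, gyroscope, nominal_rate_hz,
                             subject_id = "S00", annotations = NULL,
                             magnetometer = NULL) {
  if (nominal_rate_hz <= 0 || nominal_rate_hz > 400)
    stop("`nominal_rate_hz` must be in (0, 400]")
  if (nrow(accelerometer) != nrow(gyroscope) ||
      !isTRUE(all.equal(accelerometer$epoch_ms, gyroscope$epoch_ms)))
    stop("accelerometer and gyroscope streams are not aligned")
  if (!is.null(annotations) && nrow(annotations)) {
    ann <- annotations[order(annotations$start_ms), , drop = FALSE]
    if (any(ann$end_ms <= ann$start_ms))
      stop("annotation intervals must have end_ms > start_ms")
    if (nrow(ann) > 1L &&
        any(ann$start_ms[-1] < ann$end_ms[-nrow(ann)]))
      stop("annotation intervals overlap")
    extent <- range(accelerometer$epoch_ms)
    if (any(ann$start_ms < extent[1]) || any(ann$end_ms > extent[2] + 1))
      stop("annotations fall outside the recording extent")
    annotations <- ann
  }
  structure(list(streams = list(accelerometer = accelerometer,
                                gyroscope = gyroscope,
                                magnetometer = magnetometer),
                 nominal_rate_hz = nominal_rate_hz,
                 subject_id = subject_id,
                 annotations = annotations),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  n <- nrow(x$streams$accelerometer)
  cat(sprintf("sensor recording %s: %d samples at %g Hz, %d annotation(s)\n",
              x$subject_id, n, x$nominal_rate_hz,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

# label one window [start, end) against the annotation table: take the
# annotation with the greatest temporal overlap (ties toward the earlier
# start); BACKGROUND when nothing overlaps
.window_label <- function(start_ms, end_ms, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) return("BACKGROUND")
  ov <- pmin(end_ms, annotations$end_ms) - pmax(start_ms, annotations$start_ms)
  ov[ov < 0] <- 0
  if (all(ov == 0)) return("BACKGROUND")
  annotations$label[which.max(ov)]  # which.max keeps the earliest on ties
}

#' Segment a recording into fixed-length labeled windows
#'
#' Sliding windows of \code{window_ms} milliseconds with fractional overlap;
#' a trailing fragment shorter than the window is dropped. Channel order is
#' fixed: accelerometer x, y, z then gyroscope x, y, z. Each window carries
#' the label of the annotation overlapping it most (BACKGROUND when none
#' overlaps, ties toward the earlier annotation).
#'
#' @param recording a [sensor_recording()].
#' @param window_ms window length in milliseconds (> 0).
#' @param overlap_fraction fraction in [0, 1) shared by consecutive windows.
#' @return object of class \code{"gesture_windows"}: an \code{n_windows x
#'   window_length x 6} array plus labels and window start times. An empty
#'   recording yields zero windows.
#' @export
segment_windows <- function(recording, window_ms, overlap_fraction = 0) {
  if (window_ms <= 0) stop("`window_ms` must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)")
  acc <- recording$streams$accelerometer
  gyr <- recording$streams$gyroscope
  rate <- recording$nominal_rate_hz
  len <- as.integer(round(window_ms / 1000 * rate))
  if (len < 1L) stop("window shorter than one sample at the recording rate")
  stride <- max(1L, as.integer(round(len * (1 - overlap_fraction))))
  n <- nrow(acc)
  n_win <- if (n < len) 0L else (n - len) %/% stride + 1L
  channels <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  data <- array(NA_real_, dim = c(n_win, len, 6L),
                dimnames = list(NULL, NULL, channels))
  labels <- character(n_win)
  starts <- numeric(n_win)
  sig <- cbind(acc$x, acc$y, acc$z, gyr$x, gyr$y, gyr$z)
  for (w in seq_len(n_win)) {
    i0 <- (w - 1L) * stride + 1L
    idx <- i0:(i0 + len - 1L)
    data[w, , ] <- sig[idx, ]
    starts[w] <- acc$epoch_ms[i0]
    labels[w] <- .window_label(acc$epoch_ms[i0],
                               acc$epoch_ms[i0] + window_ms,
                               recording$annotations)
  }
  structure(list(data = data, labels = labels, starts_ms = starts,
                 window_ms = window_ms, channels = channels,
                 rate_hz = rate),
            class = "gesture_windows")
}

#' @export
print.gesture_windows <- function(x, ...) {
  cat(sprintf("%d gesture windows of %g ms (%d samples x %d channels)\n",
              dim(x$data)[1], x$window_ms, dim(x$data)[2], dim(x$data)[3]))
  if (dim(x$data)[1]) print(table(x$labels))
  invisible(x)
}

#' Labeled feature table
#'
#' The learning system's input: a fixed-width numeric feature matrix with an
#' optional label vector. No missing values are allowed.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y optional label factor/character of length \code{nrow(X)}.
#' @param feature_names optional column names to (re)apply.
#' @return an object of class \code{"feature_table"}.
#' @export
feature_table <- function(X, y = NULL, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(feature_names)) colnames(X) <- feature_names
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyNA(X)) stop("feature table must not contain missing values")
  if (!is.null(y)) {
    if (length(y) != nrow(X))
      stop("label vector length does not match the number of rows")
    if (!is.factor(y)) y <- factor(y)
  }
  structure(list(X = X, y = y, feature_names = colnames(X)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d samples x %d features\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$y)) print(table(x$y))
  invisible(x)
}

.window_feature_set <- c("mean", "sd", "min", "max", "rms")

#' Extract per-channel summary features from gesture windows
#'
#' For every channel (accelerometer block first, then gyroscope, each in
#' x, y, z order) the default feature set computes mean, SD, min, max and
#' RMS: 30 features over the six inertial channels. Column order is
#' deterministic (\code{<channel>_<statistic>}).
#'
#' @param windows a [segment_windows()] result (non-empty, uniform shape).
#' @param feature_set subset of \code{c("mean", "sd", "min", "max", "rms")}.
#' @return a [feature_table()] whose labels are the window labels.
#' @export
extract_features <- function(windows, feature_set = .window_feature_set) {
  feature_set <- match.arg(feature_set, .window_feature_set,
                           several.ok = TRUE)
  d <- dim(windows$data)
  if (d[1] < 1L) stop("no windows to featurize")
  n_win <- d[1]; len <- d[2]; n_ch <- d[3]
  cols <- list()
  for (c_i in seq_len(n_ch)) {
    M <- windows$data[, , c_i, drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = n_win)
    rm <- rowMeans(M)
    for (st in feature_set) {
      v <- switch(st,
        mean = rm,
        sd = sqrt(rowSums((M - rm)^2) / (len - 1L)),
        min = apply(M, 1L, min),
        max = apply(M, 1L, max),
        rms = sqrt(rowMeans(M^2)))
      cols[[paste(windows$channels[c_i], st, sep = "_")]] <- v
    }
  }
  X <- do.call(cbind, cols)
  feature_table(X, factor(windows$labels, levels = gesture_labels()))
}

#' Write / read a feature table as CSV
#'
#' Features at full precision plus a final \code{label} column (omitted when
#' the table is unlabeled).
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return the path ([write_feature_csv()]) or a [feature_table()]
#'   ([read_feature_csv()]).
#' @export
write_feature_csv <- function(table, path) {
  df <- as.data.frame(table$X)
  if (!is.null(table$y)) df$label <- as.character(table$y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  y <- NULL
  if ("label" %in% names(df)) {
    y <- factor(df$label,
                levels = intersect(gesture_labels(), unique(df$label)))
    if (anyNA(y)) y <- factor(df$label)
    df$label <- NULL
  }
  feature_table(as.matrix(df), y)
}
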