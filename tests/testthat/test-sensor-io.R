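test_that("sensor CSV read validates structure and ordering", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("epoch_ms,elapsed_s,x,y,z",
               "0,0,0.1,0.2,0.3",
               "10,0.01,0.4,0.5,0.6",
               "20,0.02,0.7,0.8,0.9"), p)
  s <- read_sensor_csv(p)
  expect_equal(nrow(s), 3L)
  expect_equal(s$x, c(0.1, 0.4, 0.7))
  # shuffled timestamps: ordering error naming the first violation
  writeLines(c("epoch_ms,elapsed_s,x,y,z",
               "0,0,1,1,1", "30,0.03,1,1,1", "20,0.02,1,1,1"), p)
  expect_error(read_sensor_csv(p), "row 3")
  # missing column
  writeLines(c("epoch_ms,x,y,z", "0,1,1,1"), p)
  expect_error(read_sensor_csv(p), "elapsed_s")
  # malformed rows are dropped and counted
  writeLines(c("epoch_ms,elapsed_s,x,y,z",
               "0,0,1,1,1", "10,0.01,oops,1,1", "20,0.02,1,1,1"), p)
  s <- read_sensor_csv(p)
  expect_equal(nrow(s), 2L)
  expect_equal(attr(s, "malformed"), 1L)
  expect_error(read_sensor_csv(tempfile()), "exist")
})

test_that("write/read round trip preserves values exactly", {
  set.seed(1)
  n <- 200
  df <- data.frame(epoch_ms = seq(0, by = 10, length.out = n),
                   elapsed_s = seq(0, by = 0.01, length.out = n),
                   x = stats::rnorm(n), y = stats::rnorm(n),
                   z = stats::rnorm(n))
  p <- tempfile(fileext = ".csv")
  write_sensor_csv(df, p)
  back <- read_sensor_csv(p)
  expect_identical(back$x, df$x)
  expect_identical(back$y, df$y)
  expect_identical(back$z, df$z)
  expect_identical(back$epoch_ms, df$epoch_ms)
})

test_that("recording construction enforces alignment and annotations", {
  expect_error(make_recording(rate = 500), "400")
  ann_bad <- data.frame(start_ms = c(0, 500), end_ms = c(600, 900),
                        label = c("TIP_PILL", "TOSS_PILL"))
  expect_error(make_recording(annotations = ann_bad), "overlap")
  ann_out <- data.frame(start_ms = 0, end_ms = 99999, label = "TIP_PILL")
  expect_error(make_recording(annotations = ann_out), "extent")
  ann_ok <- data.frame(start_ms = 100, end_ms = 900, label = "TIP_PILL")
  expect_s3_class(make_recording(annotations = ann_ok), "sensor_recording")
})

test_that("window counts match the closed form and brute force", {
  # 10 s at 100 Hz, 1 s windows
  rec <- make_recording(n = 1000, rate = 100)
  expect_equal(dim(segment_windows(rec, 1000, 0)$data)[1], 10L)
  expect_equal(dim(segment_windows(rec, 1000, 0.5)$data)[1], 19L)
  # brute force enumeration of window starts for several configurations
  for (cfg in list(c(730, 100, 0), c(730, 250, 0.5), c(1000, 400, 0.75),
                   c(95, 200, 0.25))) {
    n <- cfg[1]; wms <- cfg[2]; ov <- cfg[3]
    rec <- make_recording(n = n, rate = 100)
    len <- round(wms / 1000 * 100)
    stride <- max(1, round(len * (1 - ov)))
    brute <- sum(seq(1, n, by = stride) + len - 1 <= n)
    expect_equal(dim(segment_windows(rec, wms, ov)$data)[1], brute)
  }
  # an empty recording yields zero windows, not an error
  rec0 <- make_recording(n = 50, rate = 100)
  expect_equal(dim(segment_windows(rec0, 1000, 0)$data)[1], 0L)
})

test_that("windows take the label of the annotation overlapping them most", {
  # one 2 s annotation in a 10 s recording, 1 s windows, no overlap
  ann <- data.frame(start_ms = 3000, end_ms = 5000, label = "DRINK_WATER")
  rec <- make_recording(n = 1000, rate = 100, annotations = ann)
  w <- segment_windows(rec, 1000, 0)
  expect_equal(w$labels, c(rep("BACKGROUND", 3), "DRINK_WATER",
                           "DRINK_WATER", rep("BACKGROUND", 5)))
  # interval-overlap oracle on half-overlapping windows
  w2 <- segment_windows(rec, 1000, 0.5)
  oracle <- vapply(w2$starts_ms, function(s) {
    ov <- min(s + 1000, 5000) - max(s, 3000)
    if (ov > 0) "DRINK_WATER" else "BACKGROUND"
  }, character(1))
  expect_equal(w2$labels, oracle)
  # tie between two annotations resolves to the earlier start
  ann2 <- data.frame(start_ms = c(3000, 3500), end_ms = c(3400, 3900),
                     label = c("TIP_PILL", "TOSS_PILL"))
  rec2 <- make_recording(n = 1000, rate = 100, annotations = ann2)
  w3 <- segment_windows(rec2, 1000, 0)
  expect_equal(w3$labels[4], "TIP_PILL")  # window [3000, 4000): 400 ms each
})

test_that("feature extraction matches per-definition statistics", {
  # constant-zero window: every statistic zero
  rec <- make_recording(n = 300, rate = 100, fill = 0)
  ft0 <- extract_features(segment_windows(rec, 1000, 0))
  expect_true(all(ft0$X == 0))
  expect_equal(ncol(ft0$X), 30L)
  # single sinusoid on one accelerometer axis
  n <- 300
  epoch <- round((seq_len(n) - 1) / 100 * 1000)
  zero <- data.frame(epoch_ms = epoch, elapsed_s = epoch / 1000,
                     x = 0, y = 0, z = 0)
  sine <- zero
  sine$x <- sin(2 * pi * 3 * (seq_len(n) - 1) / 100)
  rec2 <- sensor_recording(sine, zero, 100)
  ft <- extract_features(segment_windows(rec2, 1000, 0))
  expect_true(all(ft$X[, "acc_x_sd"] > 0))
  expect_true(all(ft$X[, "acc_x_rms"] > 0))
  expect_true(all(ft$X[, c("acc_y_sd", "acc_z_sd", "gyro_x_rms")] == 0))
  # per-definition oracle over random windows
  set.seed(9)
  rnd <- zero
  for (cc in c("x", "y", "z")) rnd[[cc]] <- stats::rnorm(n)
  grnd <- zero
  for (cc in c("x", "y", "z")) grnd[[cc]] <- stats::rnorm(n)
  rec3 <- sensor_recording(rnd, grnd, 100)
  win <- segment_windows(rec3, 1000, 0.5)
  ft3 <- extract_features(win)
  for (w in seq_len(dim(win$data)[1])) {
    for (ci in seq_along(win$channels)) {
      v <- win$data[w, , ci]
      feat <- function(st) unname(ft3$X[w, paste0(win$channels[ci], "_", st)])
      expect_equal(feat("mean"), mean(v))
      expect_equal(feat("sd"), stats::sd(v))
      expect_equal(feat("min"), min(v))
      expect_equal(feat("max"), max(v))
      expect_equal(feat("rms"), sqrt(mean(v^2)))
    }
  }
  # permutation equivariance: permuting windows permutes rows identically
  perm <- sample(dim(win$data)[1])
  win_p <- win
  win_p$data <- win$data[perm, , , drop = FALSE]
  win_p$labels <- win$labels[perm]
  ft_p <- extract_features(win_p)
  expect_equal(ft_p$X, ft3$X[perm, ])
})

test_that("feature tables round-trip through CSV with labels", {
  ft <- small_dataset(seed = 5, subjects = 1, target = 4)
  p <- tempfile(fileext = ".csv")
  write_feature_csv(ft, p)
  back <- read_feature_csv(p)
  expect_equal(back$X, ft$X, tolerance = 1e-12)
  expect_equal(as.character(back$y), as.character(ft$y))
  # annotations side CSV
  ann <- data.frame(start_ms = c(0, 1000), end_ms = c(500, 2000),
                    label = c("TIP_PILL", "DRINK_WATER"))
  pa <- tempfile(fileext = ".csv")
  write_annotations(ann, pa)
  expect_equal(read_annotations(pa), ann)
  ann$label[1] <- "NOT_A_GESTURE"
  write_annotations(ann, pa)
  expect_error(read_annotations(pa), "unknown gesture")
})
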