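#' Signal templates for the five medication gestures
#'
#' Each gesture is a windowed sinusoid burst on a dominant sensor axis, with
#' a small fixed cross-talk fraction on a secondary axis:
#' \itemize{
#'   \item OPEN_BOTTLE / CLOSE_BOTTLE: sustained gyroscope oscillation about
#'     the forearm (x) axis with opposite mean sign and distinct frequency
#'     bands (the wrist twists in opposite directions);
#'   \item TIP_PILL: brief accelerometer pitch transient on y;
#'   \item TOSS_PILL: sharp, short accelerometer spike on x (hand to mouth);
#'   \item DRINK_WATER: slow, large accelerometer arc on z with low
#'     gyroscope energy;
#'   \item BACKGROUND: low-amplitude smoothed noise between gestures.
#' }
#' Amplitudes are in g (accelerometer) and deg/s (gyroscope); frequency in
#' Hz; duration in seconds. No two gesture templates share the same
#' (dominant axis, frequency band) pair, so the classes are separable in
#' principle; the template list itself is deterministic.
#'
#' @return named list of 5 gesture templates plus a \code{BACKGROUND}
#'   descriptor.
#' @export
default_templates <- function() {
  tpl <- function(label, sensor, axis, amp, freq, dur, dc = 0) {
    list(label = label, sensor = sensor, axis = axis,
         amp = amp, freq = freq, dur = dur, dc = dc,
         cross = 0.15)
  }
  list(
    OPEN_BOTTLE  = tpl("OPEN_BOTTLE", "gyroscope", 1L,
                       amp = c(120, 180), freq = c(3, 4), dur = c(1.5, 2.5),
                       dc = 0.5),
    TIP_PILL     = tpl("TIP_PILL", "accelerometer", 2L,
                       amp = c(0.8, 1.2), freq = c(1.5, 2.5),
                       dur = c(0.5, 0.9)),
    TOSS_PILL    = tpl("TOSS_PILL", "accelerometer", 1L,
                       amp = c(1.5, 2.5), freq = c(4, 6), dur = c(0.3, 0.6)),
    DRINK_WATER  = tpl("DRINK_WATER", "accelerometer", 3L,
                       amp = c(0.8, 1.2), freq = c(0.3, 0.6),
                       dur = c(2.5, 4)),
    CLOSE_BOTTLE = tpl("CLOSE_BOTTLE", "gyroscope", 1L,
                       amp = c(120, 180), freq = c(2, 3), dur = c(1.5, 2.5),
                       dc = -0.5),
    BACKGROUND   = list(label = "BACKGROUND", acc_sd = 0.02, gyro_sd = 1,
                        smooth = 5L)
  )
}

#' Simulation configuration
#'
#' The defaults state the emulated study conditions: 15 participants, a
#' 100 Hz device rate, 1 s analysis windows with 50\% overlap, additive
#' Gaussian sensor noise (0.05 g accelerometer, 2 deg/s gyroscope --
#' realistic wrist-IMU noise relative to gesture amplitudes of roughly 1 g
#' and 150 deg/s), and lognormal per-subject amplitude gain. Episode counts
#' per gesture are balanced by expected window yield (see
#' [balanced_episode_counts()]) with a default target of 55 windows per
#' gesture class per subject, sized so the default corpus exceeds the
#' 4116-window reference dataset.
#'
#' @param n_subjects number of simulated participants.
#' @param sample_rate_hz sampling rate (<= 100, the device streaming cap).
#' @param episodes_per_gesture \code{NULL} (balance by yield against
#'   \code{target_windows_per_class}), a single count for every gesture, or
#'   a named vector per gesture.
#' @param target_windows_per_class target labeled windows per gesture class
#'   per subject used when \code{episodes_per_gesture} is \code{NULL}.
#' @param noise_sd_acc,noise_sd_gyro additive white-noise SD per channel, in
#'   g and deg/s.
#' @param subject_gain_sd SD (log scale) of the lognormal per-subject
#'   amplitude gain.
#' @param gap_s range of the background gap between episodes, seconds.
#' @param window_ms,overlap_fraction segmentation parameters applied by
#'   [simulate_dataset()].
#' @param seed base integer seed; subject s uses \code{seed + s}.
#' @return an object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_subjects = 15L,
                              sample_rate_hz = 100,
                              episodes_per_gesture = NULL,
                              target_windows_per_class = 55,
                              noise_sd_acc = 0.05,
                              noise_sd_gyro = 2,
                              subject_gain_sd = 0.1,
                              gap_s = c(0.8, 1.5),
                              window_ms = 1000,
                              overlap_fraction = 0.5,
                              seed = 1234L) {
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  if (sample_rate_hz <= 0 || sample_rate_hz > 400)
    stop("`sample_rate_hz` must be in (0, 400]")
  if (noise_sd_acc < 0 || noise_sd_gyro < 0)
    stop("noise SDs must be non-negative")
  if (subject_gain_sd < 0) stop("`subject_gain_sd` must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects),
                 sample_rate_hz = sample_rate_hz,
                 episodes_per_gesture = episodes_per_gesture,
                 target_windows_per_class = target_windows_per_class,
                 noise_sd_acc = noise_sd_acc,
                 noise_sd_gyro = noise_sd_gyro,
                 subject_gain_sd = subject_gain_sd,
                 gap_s = as.numeric(gap_s),
                 window_ms = window_ms,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Episode counts balanced by expected window yield
#'
#' A long gesture (DRINK_WATER) covers many sliding windows per episode, a
#' short one (TOSS_PILL) very few. To keep the five gesture classes within
#' about +/-10\% of one another in the segmented corpus, the number of
#' episodes per gesture is set to \code{round(target / yield)} where the
#' expected yield per episode is \code{(mean duration + window) / stride - 1}
#' overlapping windows.
#'
#' @param templates gesture templates ([default_templates()]).
#' @param config a [simulation_config()].
#' @return named integer vector of episodes per gesture per subject.
#' @export
balanced_episode_counts <- function(templates, config) {
  g <- setdiff(names(templates), "BACKGROUND")
  if (!is.null(config$episodes_per_gesture)) {
    ep <- config$episodes_per_gesture
    if (length(ep) == 1L && is.null(names(ep)))
      return(stats::setNames(rep(as.integer(ep), length(g)), g))
    if (!all(g %in% names(ep))) stop("episodes_per_gesture must name every gesture")
    return(stats::setNames(as.integer(ep[g]), g))
  }
  win_s <- config$window_ms / 1000
  stride_s <- win_s * (1 - config$overlap_fraction)
  # windows overlapping an episode: starts range over (duration + window)
  yield <- vapply(templates[g], function(t)
    (mean(t$dur) + win_s) / stride_s, numeric(1))
  counts <- pmax(1L, as.integer(round(config$target_windows_per_class / yield)))
  stats::setNames(counts, g)
}

# one raised-cosine-windowed sinusoid burst
.burst <- function(len, rate, amp, freq, dc, phase) {
  tt <- seq_len(len) / rate
  env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1L)))
  (amp * sin(2 * pi * freq * tt + phase) + dc * amp) * env
}

#' Simulate one annotated multi-sensor recording
#'
#' Gesture episodes (counts per [balanced_episode_counts()]) are shuffled
#' into a random order and separated by background gaps. The accelerometer
#' carries a 1 g gravity baseline on z; each episode adds its template burst
#' (scaled by the subject's lognormal gain) on the dominant axis plus 15\%
#' cross-talk on the next axis; smoothed low-amplitude background motion and
#' white sensor noise are added throughout. Ground-truth annotations cover
#' exactly the scheduled episodes.
#'
#' @param templates gesture templates from [default_templates()].
#' @param config a [simulation_config()].
#' @param subject_id identifier stored in the recording.
#' @param seed integer seed for this recording (defaults to the config seed).
#' @return a [sensor_recording()] with annotations.
#' @export
simulate_recording <- function(templates, config, subject_id = "S01",
                               seed = config$seed) {
  set.seed(seed)
  rate <- config$sample_rate_hz
  gain <- stats::rlnorm(1, 0, config$subject_gain_sd)
  counts <- balanced_episode_counts(templates, config)
  labels <- sample(rep(names(counts), counts))
  n_ep <- length(labels)
  durs <- vapply(labels, function(l)
    stats::runif(1, templates[[l]]$dur[1], templates[[l]]$dur[2]), numeric(1))
  gaps <- stats::runif(n_ep + 1L, config$gap_s[1], config$gap_s[2])
  # sample index schedule
  total_s <- sum(durs) + sum(gaps)
  n <- as.integer(ceiling(total_s * rate)) + 1L
  acc <- matrix(0, n, 3L)
  gyr <- matrix(0, n, 3L)
  acc[, 3L] <- 1  # gravity baseline on z, in g
  start_ms <- numeric(n_ep); end_ms <- numeric(n_ep)
  cursor <- gaps[1]
  for (e in seq_len(n_ep)) {
    tp <- templates[[labels[e]]]
    i0 <- as.integer(floor(cursor * rate)) + 1L
    len <- max(2L, as.integer(round(durs[e] * rate)))
    idx <- i0:min(n, i0 + len - 1L)
    amp <- stats::runif(1, tp$amp[1], tp$amp[2]) * gain
    freq <- stats::runif(1, tp$freq[1], tp$freq[2])
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- .burst(length(idx), rate, amp, freq, tp$dc, phase)
    sec <- tp$axis %% 3L + 1L
    if (tp$sensor == "accelerometer") {
      acc[idx, tp$axis] <- acc[idx, tp$axis] + wave
      acc[idx, sec] <- acc[idx, sec] + tp$cross * wave
    } else {
      gyr[idx, tp$axis] <- gyr[idx, tp$axis] + wave
      gyr[idx, sec] <- gyr[idx, sec] + tp$cross * wave
    }
    start_ms[e] <- round((i0 - 1L) / rate * 1000)
    end_ms[e] <- round((i0 - 1L + length(idx)) / rate * 1000)
    cursor <- cursor + durs[e] + gaps[e + 1L]
  }
  # smoothed background motion everywhere, then white sensor noise
  bg <- templates$BACKGROUND
  smooth <- function(x, k) as.numeric(stats::filter(x, rep(1 / k, k),
                                                    sides = 2L,
                                                    circular = TRUE))
  for (a in 1:3) {
    acc[, a] <- acc[, a] + smooth(stats::rnorm(n, 0, bg$acc_sd), bg$smooth)
    gyr[, a] <- gyr[, a] + smooth(stats::rnorm(n, 0, bg$gyro_sd), bg$smooth)
  }
  if (config$noise_sd_acc > 0)
    acc <- acc + stats::rnorm(3L * n, 0, config$noise_sd_acc)
  if (config$noise_sd_gyro > 0)
    gyr <- gyr + stats::rnorm(3L * n, 0, config$noise_sd_gyro)
  epoch_ms <- round((seq_len(n) - 1L) / rate * 1000)
  mk <- function(m) data.frame(epoch_ms = epoch_ms,
                               elapsed_s = epoch_ms / 1000,
                               x = m[, 1], y = m[, 2], z = m[, 3])
  ann <- data.frame(start_ms = start_ms, end_ms = end_ms, label = labels,
                    stringsAsFactors = FALSE)
  sensor_recording(mk(acc), mk(gyr), nominal_rate_hz = rate,
                   subject_id = subject_id, annotations = ann)
}

#' Simulate a labeled multi-subject feature corpus
#'
#' Runs [simulate_recording()] for every subject, segments each recording
#' with the config's window settings and extracts the default feature set,
#' returning one pooled [feature_table()]. When \code{dir} is given, the
#' per-subject sensor CSVs, annotation CSVs, the pooled feature CSV and a
#' manifest listing every emitted file (with the seed used) are written
#' there.
#'
#' @param config a [simulation_config()].
#' @param templates gesture templates (default [default_templates()]).
#' @param dir optional output directory for the CSV corpus.
#' @return a [feature_table()] with attributes \code{class_counts} and
#'   \code{subject} (per-row subject id).
#' @export
simulate_dataset <- function(config = simulation_config(),
                             templates = default_templates(),
                             dir = NULL) {
  tables <- vector("list", config$n_subjects)
  subjects <- character(0)
  manifest <- character(0)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    seed_s <- (config$seed + s) %% .Machine$integer.max
    rec <- simulate_recording(templates, config, subject_id = sid,
                              seed = seed_s)
    win <- segment_windows(rec, config$window_ms, config$overlap_fraction)
    ft <- extract_features(win)
    tables[[s]] <- ft
    subjects <- c(subjects, rep(sid, nrow(ft$X)))
    if (!is.null(dir)) {
      pa <- file.path(dir, paste0(sid, "_accelerometer.csv"))
      pg <- file.path(dir, paste0(sid, "_gyroscope.csv"))
      pn <- file.path(dir, paste0(sid, "_annotations.csv"))
      write_sensor_csv(rec$streams$accelerometer, pa)
      write_sensor_csv(rec$streams$gyroscope, pg)
      write_annotations(rec$annotations, pn)
      manifest <- c(manifest,
                    sprintf("%s,%s,%d", sid, basename(pa), seed_s),
                    sprintf("%s,%s,%d", sid, basename(pg), seed_s),
                    sprintf("%s,%s,%d", sid, basename(pn), seed_s))
    }
  }
  X <- do.call(rbind, lapply(tables, function(t) t$X))
  y <- factor(unlist(lapply(tables, function(t) as.character(t$y))),
              levels = gesture_labels())
  out <- feature_table(X, y)
  attr(out, "class_counts") <- table(y)
  attr(out, "subject") <- subjects
  if (!is.null(dir)) {
    write_feature_csv(out, file.path(dir, "features.csv"))
    writeLines(c("subject,file,seed", manifest,
                 sprintf("all,features.csv,%d", config$seed)),
               file.path(dir, "MANIFEST.csv"))
  }
  out
}
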