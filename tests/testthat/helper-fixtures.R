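# shared fixtures, all generated in code

# two well-separated Gaussian blobs, z-scored
make_blob <- function(seed, n_per_class = 30) {
  set.seed(seed)
  x <- rbind(cbind(stats::rnorm(n_per_class, -2, 0.5),
                   stats::rnorm(n_per_class, -2, 0.5)),
             cbind(stats::rnorm(n_per_class, 2, 0.5),
                   stats::rnorm(n_per_class, 2, 0.5)))
  list(x = scale(x), y = factor(rep(c("A", "B"), each = n_per_class)))
}

# hand-built recording: constant streams at a given rate, optional annotations
make_recording <- function(n = 1000, rate = 100, annotations = NULL,
                           fill = 0) {
  epoch <- round((seq_len(n) - 1L) / rate * 1000)
  df <- function(v) data.frame(epoch_ms = epoch, elapsed_s = epoch / 1000,
                               x = v, y = v, z = v)
  sensor_recording(df(rep(fill, n)), df(rep(fill, n)), nominal_rate_hz = rate,
                   annotations = annotations)
}

# small synthetic corpus used by evaluation/cli tests
small_dataset <- function(seed = 77, subjects = 3, target = 12,
                          noise_acc = 0.05, noise_gyro = 2) {
  cfg <- simulation_config(n_subjects = subjects,
                           target_windows_per_class = target,
                           noise_sd_acc = noise_acc,
                           noise_sd_gyro = noise_gyro, seed = seed)
  simulate_dataset(cfg)
}

# fast training configuration for pipeline tests
quick_config <- function(seed = 1, ...) {
  training_config(pop_size = 10L, max_iter = 20L, epochs = 100L,
                  seed = seed, ...)
}
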