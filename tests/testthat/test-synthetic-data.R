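test_that("schedule conservation: recording count matches the design", {
  cfg <- tiny_config(n_subjects = 2, n_days = 2, n_gestures = 2,
                     n_trials = 2, n_movements = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds$recordings, 2 * 2 * 2 * 2 * 3)
  expect_true(all(ds$ground_truth$gesture %in% cfg$gestures))
  # full default schedules, counted without synthesis
  expect_equal(nrow(dataset_schedule(generator_config())) / 20, 132)
  expect_equal(nrow(dataset_schedule(generator_config(
    gesture_set = "daily_use"))) / 20, 120)
})

test_that("gesture models: jitter-free subjects identical, seeded reruns identical", {
  m0 <- build_gesture_models("single_dof", n_subjects = 3,
                             intersubject_jitter = 0, seed = 5)
  expect_identical(m0[[1]], m0[[2]])
  expect_identical(m0[[2]], m0[[3]])
  expect_length(m0[[1]], 11)
  expect_length(build_gesture_models("daily_use", n_subjects = 1,
                                     seed = 5)[[1]], 10)
  m1 <- build_gesture_models("single_dof", n_subjects = 3, seed = 9)
  m2 <- build_gesture_models("single_dof", n_subjects = 3, seed = 9)
  expect_identical(m1, m2)
  # jittered subjects differ
  expect_false(identical(m1[[1]], m1[[2]]))
})

test_that("a narrow source maximizes RMS at its own electrode", {
  cfg <- tiny_config(line_amp = 0, drift_amp = 0, snr_db = 40,
                     source_spread = 0.8)
  layout <- build_layout()
  model <- list(gesture_id = "probe",
                sources = data.frame(row_center = 2, col_center = 4,
                                     spread = 0.8, gain = 1))
  target <- layout$channel[layout$side == "flexor" & layout$row == 2 &
                             layout$col == 4]
  hits <- vapply(1:20, function(s) {
    rec <- synthesize_movement(model, cfg, seed = s, layout = layout)
    which.max(sqrt(colMeans(rec$signal^2)))
  }, numeric(1))
  expect_true(all(hits == target))
})

test_that("null sources and zero noise give an all-zero epoch", {
  cfg <- tiny_config(line_amp = 0, drift_amp = 0, snr_db = Inf)
  model <- list(gesture_id = "null",
                sources = data.frame(row_center = 8, col_center = 8,
                                     spread = 2, gain = 0))
  rec <- synthesize_movement(model, cfg, seed = 1)
  expect_equal(dim(rec$signal), c(2048, 256))
  expect_true(all(rec$signal == 0))
})

test_that("clean channels concentrate >= 90% of power in 20-450 Hz", {
  cfg <- tiny_config(line_amp = 0, drift_amp = 0, snr_db = 10)
  models <- build_gesture_models("single_dof", cfg$gestures, 1, seed = 3)
  rec <- synthesize_movement(models[[1]][[2]], cfg, seed = 11)
  n <- nrow(rec$signal)
  f <- cfg$fs * (seq_len(n %/% 2 + 1) - 1) / n
  # Hann taper keeps rectangular-window sidelobe leakage out of the measure
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  P <- Mod(stats::mvfft(rec$signal * w))^2
  P <- P[seq_len(n %/% 2 + 1), ]
  frac <- colSums(P[f >= 20 & f <= 450, ]) / colSums(P)
  expect_true(all(frac >= 0.9))
})

test_that("bad-channel injection respects the flag probability and corrupts hard", {
  base <- structure(list(signal = matrix(rnorm(64 * 256, 0, 0.05), 64, 256),
                         fs = 2048, meta = list()),
                    class = "emg_recording")
  expect_identical(inject_bad_channels(base, 0, seed = 1)$bad_channels,
                   integer(0))
  expect_length(inject_bad_channels(base, 1, seed = 1)$bad_channels, 256)
  # binomial concentration: ~10,000 draws at p = 0.05
  n_flagged <- sum(vapply(1:40, function(s) {
    length(inject_bad_channels(base, 0.05, seed = s)$bad_channels)
  }, numeric(1)))
  expect_gt(n_flagged / (40 * 256), 0.04)
  expect_lt(n_flagged / (40 * 256), 0.06)
  # corrupted channels carry >= 10x the clean RMS
  inj <- inject_bad_channels(base, 0.2, seed = 2)
  for (ch in inj$bad_channels) {
    expect_gte(sqrt(mean(inj$recording$signal[, ch]^2)),
               10 * sqrt(mean(base$signal[, ch]^2)))
  }
})

test_that("dataset regeneration with the same seed is identical", {
  cfg <- tiny_config(n_gestures = 2, movement_duration = 0.5,
                     p_bad_channel = 0.1)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  cfg2 <- tiny_config(n_gestures = 2, movement_duration = 0.5,
                      p_bad_channel = 0.1, seed = 124)
  expect_false(identical(generate_dataset(cfg)$recordings[[1]]$signal,
                         generate_dataset(cfg2)$recordings[[1]]$signal))
})

test_that("dataset writer/reader round-trips and serializes deterministically", {
  cfg <- tiny_config(n_gestures = 2, movement_duration = 0.25,
                     p_bad_channel = 0.3)
  ds <- generate_dataset(cfg)
  d1 <- file.path(tempdir(), "emg_ds1")
  d2 <- file.path(tempdir(), "emg_ds2")
  write_dataset(ds, d1)
  write_dataset(ds, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_dataset(d1)
  expect_equal(length(back$recordings), length(ds$recordings))
  expect_equal(back$recordings[[1]]$signal, ds$recordings[[1]]$signal,
               tolerance = 1e-12)
  expect_equal(back$ground_truth$gesture, ds$ground_truth$gesture)
  expect_equal(unclass(back$ground_truth$bad_channels),
               unclass(ds$ground_truth$bad_channels))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_subjects = 0))
  expect_error(generator_config(fs = 800))
  expect_error(generator_config(p_bad_channel = 1.5))
  expect_error(generator_config(snr_db = NaN), "non-finite")
  expect_error(generator_config(gesture_set = "grip_set"))
})
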