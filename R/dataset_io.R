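#' Write a synthetic dataset to a plain-text directory
#'
#' Layout: `config.json` and `layout.csv` at the top level,
#' `ground_truth.csv` (labels and corrupted-channel lists), and one
#' `recordings/s<subject>_d<day>_<k>.csv` file per movement epoch (samples
#' x 256 channels, volts). The format is self-describing and
#' deterministic, so re-serializing the same dataset is byte-identical.
#'
#' @param dataset An `emg_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  cfg <- dataset$config
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(dataset$layout), file.path(dir, "layout.csv"),
            row.names = FALSE)
  gt <- dataset$ground_truth
  gt$bad_channels <- vapply(gt$bad_channels, function(v) {
    paste(v, collapse = ";")
  }, character(1))
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  for (i in seq_along(dataset$recordings)) {
    rec <- dataset$recordings[[i]]
    fn <- sprintf("s%02d_d%d_%04d.csv", rec$meta$subject, rec$meta$day, i)
    write.csv(rec$signal, file.path(dir, "recordings", fn),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return An `emg_dataset`.
#' @export
read_dataset <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- generator_config(
    n_subjects = cfg_raw$n_subjects, n_days = cfg_raw$n_days,
    gesture_set = cfg_raw$gesture_set,
    n_gestures = length(cfg_raw$gestures),
    n_trials = cfg_raw$n_trials, n_movements = cfg_raw$n_movements,
    fs = cfg_raw$fs, movement_duration = cfg_raw$movement_duration,
    snr_db = cfg_raw$snr_db, line_amp = cfg_raw$line_amp,
    drift_amp = cfg_raw$drift_amp, p_bad_channel = cfg_raw$p_bad_channel,
    interday_shift_rows = cfg_raw$interday_shift_rows,
    intersubject_jitter = cfg_raw$intersubject_jitter,
    amplitude_scale = cfg_raw$amplitude_scale,
    source_spread = cfg_raw$source_spread, seed = cfg_raw$seed)
  layout <- build_layout()
  gt <- read.csv(file.path(dir, "ground_truth.csv"),
                 stringsAsFactors = FALSE)
  bad <- lapply(gt$bad_channels, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";")[[1]])
  })
  gt$bad_channels <- I(bad)
  files <- sprintf("s%02d_d%d_%04d.csv", gt$subject, gt$day,
                   seq_len(nrow(gt)))
  recordings <- lapply(seq_len(nrow(gt)), function(i) {
    sig <- as.matrix(read.csv(file.path(dir, "recordings", files[i])))
    dimnames(sig) <- NULL
    structure(list(signal = sig, fs = cfg$fs,
                   meta = list(subject = gt$subject[i], day = gt$day[i],
                               gesture = gt$gesture[i], trial = gt$trial[i],
                               movement = gt$movement[i])),
              class = "emg_recording")
  })
  structure(list(recordings = recordings, layout = layout, config = cfg,
                 ground_truth = gt),
            class = "emg_dataset")
}
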