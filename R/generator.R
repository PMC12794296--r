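#' Gesture vocabularies
#'
#' Two gesture groups are supported: 11 single-degree-of-freedom movements
#' and 10 compound daily-use movements.
#'
#' @param gesture_set `"single_dof"` or `"daily_use"`.
#' @return Character vector of gesture labels.
#' @export
gesture_names <- function(gesture_set = c("single_dof", "daily_use")) {
  gesture_set <- match.arg(gesture_set)
  if (gesture_set == "single_dof") {
    c("thumb_extension", "index_extension", "middle_extension",
      "ring_extension", "little_extension", "wrist_flexion",
      "wrist_extension", "wrist_radial", "wrist_ulnar",
      "wrist_pronation", "wrist_supination")
  } else {
    c("wrist_flexion", "wrist_extension", "wrist_radial", "wrist_ulnar",
      "wrist_pronation", "wrist_supination", "hand_close", "hand_open",
      "thumb_index_pinch", "thumb_middle_pinch")
  }
}

#' Synthetic HD-sEMG generator configuration
#'
#' Defines the acquisition schedule and signal phenomenology of the
#' synthetic dataset: 20 subjects x 2 days, each gesture executed in 2
#' trials of 3 one-second dynamic movements per day, sampled at 2048 Hz on
#' the 256-channel montage. Amplitudes are expressed in post-amplifier
#' volts, with the strongest channel of an active source reaching an RMS of
#' about `amplitude_scale` (default 0.1 V) so that the standard myopulse /
#' Willison thresholds of 0.05 V are meaningful.
#'
#' @param n_subjects,n_days,n_trials,n_movements Schedule counts.
#' @param gesture_set `"single_dof"` (11 gestures) or `"daily_use"` (10).
#' @param n_gestures Optional count to restrict to the first `n_gestures`
#'   gestures of the set (reduced-scale experiments); `NULL` uses all.
#' @param fs Sampling rate, Hz.
#' @param movement_duration Movement epoch length, seconds.
#' @param snr_db Ratio (dB) of the peak-channel clean EMG RMS to the
#'   per-channel sensor-noise RMS.
#' @param line_amp Amplitude (V) of the 50 Hz mains fundamental; harmonics
#'   up to 400 Hz decay as 1/k.
#' @param drift_amp Baseline-drift amplitude, V (low-frequency, < 1 Hz).
#' @param p_bad_channel Per-channel corruption probability.
#' @param interday_shift_rows Electrode-row displacement applied to all
#'   source centres on days after the first (micro-shift of the arrays).
#' @param intersubject_jitter List with `center_sd` (electrode pitches) and
#'   `gain_sd` (log-scale) controlling anatomical variability across
#'   subjects; a single scalar `0` disables it.
#' @param amplitude_scale Post-gain EMG amplitude scale, V.
#' @param source_spread Spatial decay scale of a source's surface
#'   potential, in electrode pitches.
#' @param seed Global integer seed; all per-subject/day/movement random
#'   streams are derived deterministically from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_subjects = 20, n_days = 2,
                             gesture_set = c("single_dof", "daily_use"),
                             n_gestures = NULL,
                             n_trials = 2, n_movements = 3,
                             fs = 2048, movement_duration = 1.0,
                             snr_db = 10, line_amp = 0.02, drift_amp = 0.05,
                             p_bad_channel = 0.02,
                             interday_shift_rows = 0.5,
                             intersubject_jitter = list(center_sd = 1.0,
                                                        gain_sd = 0.3),
                             amplitude_scale = 0.1, source_spread = 2.0,
                             seed = 1L) {
  gesture_set <- match.arg(gesture_set)
  gestures <- gesture_names(gesture_set)
  if (!is.null(n_gestures)) {
    stopifnot(n_gestures >= 1, n_gestures <= length(gestures))
    gestures <- gestures[seq_len(n_gestures)]
  }
  if (is.numeric(intersubject_jitter) && length(intersubject_jitter) == 1) {
    intersubject_jitter <- list(center_sd = intersubject_jitter,
                                gain_sd = intersubject_jitter)
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_days = as.integer(n_days),
              gesture_set = gesture_set, gestures = gestures,
              n_trials = as.integer(n_trials),
              n_movements = as.integer(n_movements),
              fs = fs, movement_duration = movement_duration,
              snr_db = snr_db, line_amp = line_amp, drift_amp = drift_amp,
              p_bad_channel = p_bad_channel,
              interday_shift_rows = interday_shift_rows,
              intersubject_jitter = intersubject_jitter,
              amplitude_scale = amplitude_scale,
              source_spread = source_spread,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_subjects >= 1, n_days >= 1, n_trials >= 1, n_movements >= 1,
              fs > 2 * 500, movement_duration > 0,
              p_bad_channel >= 0, p_bad_channel <= 1)
  })
  num <- unlist(cfg[c("fs", "movement_duration", "line_amp",
                      "drift_amp", "amplitude_scale", "source_spread",
                      "interday_shift_rows")])
  # snr_db = Inf is a valid noise-free limit; NaN/NA are not
  if (!all(is.finite(num)) || is.na(cfg$snr_db)) {
    stop("non-finite generator configuration value")
  }
  class(cfg) <- "generator_config"
  cfg
}

# deterministic sub-seed derivation from integer components
mix_seed <- function(...) {
  v <- c(...)
  h <- 17
  for (x in v) h <- (h * 131 + (as.numeric(x) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# deterministic base source models for a gesture vocabulary: single-DoF
# gestures are driven by sources near the wrist (distal rows), compound
# daily-use gestures by mid/proximal sources, encoding the premise that
# extrinsic hand muscles concentrate distally.
base_gesture_models <- function(gesture_set, gestures, source_spread = 2.0) {
  K <- length(gestures)
  row_base <- if (gesture_set == "single_dof") 1.5 else 11
  lapply(seq_len(K), function(g) {
    col1 <- 1.5 + 13 * (if (K > 1) (g - 1) / (K - 1) else 0)
    row1 <- row_base + 2 * ((g - 1) %% 3)
    col2 <- ((col1 + 6.5 - 1) %% 15) + 1
    row2 <- min(16, row1 + 1.5)
    list(gesture_id = gestures[g],
         sources = data.frame(
           row_center = c(row1, row2), col_center = c(col1, col2),
           spread = source_spread, gain = c(1, 0.5)))
  })
}

#' Build per-subject gesture source models
#'
#' Each gesture is modelled as a small set of cutaneous activity sources on
#' the 16 x 16 (axial row x circumferential position) electrode grid, with a
#' Gaussian spatial footprint. Single-DoF gestures have distally biased row
#' centres; daily-use gestures mid/proximally biased ones. Subjects differ
#' by jittered source centres and log-normal gain factors.
#'
#' @param gesture_set,gestures Gesture vocabulary (`gestures` defaults to
#'   the full set).
#' @param n_subjects Number of subjects to instantiate.
#' @param intersubject_jitter List with `center_sd` and `gain_sd`, or
#'   scalar 0.
#' @param source_spread Spatial decay scale (pitches).
#' @param seed Integer seed.
#' @return List (one element per subject) of lists of `gesture_source_model`
#'   objects (`gesture_id` + `sources` data frame).
#' @export
build_gesture_models <- function(gesture_set = c("single_dof", "daily_use"),
                                 gestures = NULL, n_subjects = 1,
                                 intersubject_jitter = list(center_sd = 1.0,
                                                            gain_sd = 0.3),
                                 source_spread = 2.0, seed = 1L) {
  gesture_set <- match.arg(gesture_set)
  if (is.null(gestures)) gestures <- gesture_names(gesture_set)
  if (length(gestures) < 1) stop("empty gesture set")
  if (is.numeric(intersubject_jitter) && length(intersubject_jitter) == 1) {
    intersubject_jitter <- list(center_sd = intersubject_jitter,
                                gain_sd = intersubject_jitter)
  }
  base <- base_gesture_models(gesture_set, gestures, source_spread)
  lapply(seq_len(n_subjects), function(s) {
    set.seed(mix_seed(seed, 101, s))
    lapply(base, function(m) {
      ns <- nrow(m$sources)
      m$sources$row_center <- pmin(16, pmax(1,
        m$sources$row_center + rnorm(ns, 0, intersubject_jitter$center_sd)))
      m$sources$col_center <- pmin(16, pmax(1,
        m$sources$col_center + rnorm(ns, 0, intersubject_jitter$center_sd)))
      m$sources$gain <- m$sources$gain *
        exp(rnorm(ns, 0, intersubject_jitter$gain_sd))
      m
    })
  })
}

# trapezoidal activation envelope: 0.25 s reaction-phase rise, plateau,
# 0.1 s release
activation_envelope <- function(n, fs, rise = 0.25, fall = 0.1) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  env <- rep(1, n)
  env[t < rise] <- t[t < rise] / rise
  tail <- t > dur - fall
  env[tail] <- pmax(0, (dur - t[tail]) / fall)
  env
}

# spatial gain of each layout channel for each source (Gaussian decay of
# grid distance; circumferential position 1..16 = flexor 1-8, extensor 9-16)
source_gain_matrix <- function(layout, sources) {
  circ <- ifelse(layout$side == "flexor", layout$col, 8L + layout$col)
  G <- matrix(0, nrow(layout), nrow(sources))
  for (j in seq_len(nrow(sources))) {
    d2 <- (layout$row - sources$row_center[j])^2 +
      (circ - sources$col_center[j])^2
    G[, j] <- sources$gain[j] * exp(-d2 / (2 * sources$spread[j]^2))
  }
  G
}

# 20-450 Hz band-limiting filter used for EMG carriers and sensor noise
emg_band_coeffs <- function(fs) {
  signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
}

#' Synthesize one movement epoch
#'
#' Produces a 256-channel epoch of `fs * movement_duration` samples: each
#' source emits a band-limited (20-450 Hz) Gaussian carrier modulated by a
#' trapezoidal activation envelope and projected onto the grid through its
#' Gaussian spatial footprint; 50 Hz mains interference plus harmonics up to
#' 400 Hz (1/k amplitude decay, random phases), low-frequency baseline
#' drift, and band-limited sensor noise are added. On days after the first,
#' source row centres are displaced by `interday_shift_rows` and gains
#' perturbed, emulating array re-placement.
#'
#' @param model A `gesture_source_model`.
#' @param config A [generator_config()].
#' @param day Recording day (1-based).
#' @param seed Integer seed for this epoch's random streams.
#' @param day_seed Seed controlling the day-level placement perturbation
#'   (shared across all movements of a subject-day); derived from `seed`
#'   and `day` when `NULL`.
#' @param layout Electrode layout (built once and reused by callers).
#' @return An `emg_recording`: list with `signal` (samples x 256 channels,
#'   volts), `fs`, and `meta` (`gesture` label; callers fill the rest).
#' @export
synthesize_movement <- function(model, config, day = 1, seed = 1L,
                                day_seed = NULL, layout = build_layout()) {
  fs <- config$fs
  n <- round(fs * config$movement_duration)
  sources <- model$sources
  if (day > config$n_days) stop("day exceeds configured n_days")
  if (day > 1) {
    if (is.null(day_seed)) day_seed <- mix_seed(seed, 211, day)
    set.seed(day_seed)
    sources$row_center <- pmin(16, pmax(1,
      sources$row_center + config$interday_shift_rows))
    sources$gain <- sources$gain * exp(rnorm(nrow(sources), 0, 0.1))
  }
  set.seed(seed)
  bp <- emg_band_coeffs(fs)
  env <- activation_envelope(n, fs)
  nsrc <- nrow(sources)
  sig <- matrix(0, n, 256)
  active <- sources$gain > 0
  if (any(active)) {
    carriers <- matrix(rnorm(n * nsrc), n, nsrc)
    carriers <- zerophase_filter_cpp(bp$b, bp$a, carriers)
    carriers <- sweep(carriers, 2, sqrt(colMeans(carriers^2)), "/")
    G <- source_gain_matrix(layout, sources)
    sig <- (carriers * env) %*% t(G) * config$amplitude_scale
  }
  if (config$line_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    line <- numeric(n)
    for (k in seq_len(floor(400 / 50))) {
      line <- line + (config$line_amp / k) *
        sin(2 * pi * 50 * k * t + runif(1, 0, 2 * pi))
    }
    sig <- sig + line
  }
  if (config$drift_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    shape <- sin(2 * pi * runif(1, 0.2, 1) * t + runif(1, 0, 2 * pi))
    coef <- config$drift_amp * runif(256, 0.5, 1) * sample(c(-1, 1), 256, TRUE)
    sig <- sig + outer(shape, coef)
  }
  noise_sd <- config$amplitude_scale * 10^(-config$snr_db / 20)
  if (noise_sd > 0) {
    noise <- matrix(rnorm(n * 256), n, 256)
    noise <- zerophase_filter_cpp(bp$b, bp$a, noise)
    noise <- noise * (noise_sd / sqrt(mean(noise^2)))
    sig <- sig + noise
  }
  structure(list(signal = sig, fs = fs,
                 meta = list(gesture = model$gesture_id, day = day)),
            class = "emg_recording")
}

#' Inject corrupted channels
#'
#' Each channel is independently flagged with probability `p`; flagged
#' channels receive either a large constant offset or strongly amplified
#' noise (both at least 10x the clean channel's RMS), emulating abrupt
#' baseline jumps and poor electrode-skin contact.
#'
#' @param recording An `emg_recording`.
#' @param p Corruption probability per channel.
#' @param seed Integer seed.
#' @return List with the modified `recording` and integer vector
#'   `bad_channels` of flagged channel ids.
#' @export
inject_bad_channels <- function(recording, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  nch <- ncol(recording$signal)
  set.seed(seed)
  flags <- which(runif(nch) < p)
  for (ch in flags) {
    x <- recording$signal[, ch]
    base <- max(sqrt(mean(x^2)), 1e-3)
    if (runif(1) < 0.5) {
      recording$signal[, ch] <- x + 15 * base
    } else {
      nz <- rnorm(length(x))
      nz <- nz / sqrt(mean(nz^2)) * 12 * base  # realized RMS exactly 12x
      recording$signal[, ch] <- x + nz
    }
  }
  list(recording = recording, bad_channels = flags)
}

#' Recording schedule implied by a generator configuration
#'
#' @param config A [generator_config()].
#' @return Data frame with one row per movement epoch: `subject`, `day`,
#'   `gesture`, `trial`, `movement`.
#' @export
dataset_schedule <- function(config) {
  sch <- expand.grid(movement = seq_len(config$n_movements),
                     trial = seq_len(config$n_trials),
                     gesture = config$gestures,
                     day = seq_len(config$n_days),
                     subject = seq_len(config$n_subjects),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sch <- sch[, c("subject", "day", "gesture", "trial", "movement")]
  rownames(sch) <- NULL
  sch
}

#' Generate a full synthetic HD-sEMG dataset
#'
#' Realizes the complete acquisition schedule (subjects x days x gestures x
#' trials x movements) with per-subject source models, inter-day array
#' micro-shift and per-channel corruption. Regeneration with the same
#' configuration (including seed) is bit-identical.
#'
#' @param config A [generator_config()].
#' @return An `emg_dataset`: list with `recordings` (list of
#'   `emg_recording`), `layout`, `config` and `ground_truth` (data frame of
#'   per-recording labels plus a `bad_channels` list column).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  layout <- build_layout()
  models <- build_gesture_models(config$gesture_set, config$gestures,
                                 config$n_subjects,
                                 config$intersubject_jitter,
                                 config$source_spread,
                                 seed = mix_seed(config$seed, 1))
  sch <- dataset_schedule(config)
  recordings <- vector("list", nrow(sch))
  bad <- vector("list", nrow(sch))
  for (i in seq_len(nrow(sch))) {
    s <- sch$subject[i]; d <- sch$day[i]
    g <- match(sch$gesture[i], config$gestures)
    rec_seed <- mix_seed(config$seed, s, d, g, sch$trial[i], sch$movement[i])
    day_seed <- mix_seed(config$seed, 211, s, d)
    rec <- synthesize_movement(models[[s]][[g]], config, day = d,
                               seed = rec_seed, day_seed = day_seed,
                               layout = layout)
    inj <- inject_bad_channels(rec, config$p_bad_channel,
                               seed = mix_seed(rec_seed, 7))
    rec <- inj$recording
    rec$meta <- list(subject = s, day = d, gesture = sch$gesture[i],
                     trial = sch$trial[i], movement = sch$movement[i])
    recordings[[i]] <- rec
    bad[[i]] <- inj$bad_channels
  }
  gt <- cbind(sch, n_bad = vapply(bad, length, integer(1)))
  gt$bad_channels <- I(bad)
  structure(list(recordings = recordings, layout = layout, config = config,
                 ground_truth = gt),
            class = "emg_dataset")
}
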