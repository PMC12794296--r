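# coerce recording-or-matrix input to a samples x channels matrix
as_signal_matrix <- function(x) {
  if (inherits(x, "emg_recording")) x$signal
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), ncol = 1)
}

restore_signal <- function(x, sig) {
  if (inherits(x, "emg_recording")) {
    x$signal <- sig
    x
  } else if (is.matrix(x)) sig else drop(sig)
}

#' Butterworth band-pass filter (zero-phase)
#'
#' Applies the acquisition band-pass (default 10-500 Hz, order-8
#' Butterworth) forward and backward (zero-phase), so the 0.25 s
#' reaction-phase trim boundary is not displaced by group delay. The design
#' order refers to the band-pass transfer function itself; the effective
#' attenuation doubles under forward-backward application.
#'
#' @param x An `emg_recording`, samples-x-channels matrix, or vector.
#' @param fs Sampling rate (taken from the recording when available).
#' @param low,high Band edges, Hz.
#' @param order Band-pass filter order (even).
#' @return Same shape as `x`, filtered per channel.
#' @export
bandpass <- function(x, fs = NULL, low = 10, high = 500, order = 8) {
  if (is.null(fs)) {
    if (!inherits(x, "emg_recording")) stop("fs required for matrix input")
    fs <- x$fs
  }
  if (high >= fs / 2) stop("high cutoff must be below the Nyquist frequency")
  if (low <= 0 || low >= high) stop("invalid band edges")
  if (order %% 2 != 0) stop("band-pass order must be even")
  bw <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  sig <- zerophase_filter_cpp(bw$b, bw$a, as_signal_matrix(x))
  restore_signal(x, sig)
}

# second-order IIR notch (constrained biquad), centre f0, quality q
notch_coeffs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

#' Powerline notch comb (zero-phase)
#'
#' Cascade of second-order IIR notches at the mains fundamental and its
#' harmonics (default 50, 100, ..., 400 Hz), each applied zero-phase.
#'
#' @param x An `emg_recording`, samples-x-channels matrix, or vector.
#' @param fs Sampling rate.
#' @param base Mains fundamental, Hz.
#' @param max_freq Highest harmonic to notch, Hz.
#' @param q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return Same shape as `x`.
#' @export
notch_comb <- function(x, fs = NULL, base = 50, max_freq = 400, q = 30) {
  if (is.null(fs)) {
    if (!inherits(x, "emg_recording")) stop("fs required for matrix input")
    fs <- x$fs
  }
  if (base > max_freq || max_freq >= fs / 2) stop("invalid notch range")
  sig <- as_signal_matrix(x)
  for (f0 in seq(base, max_freq, by = base)) {
    nc <- notch_coeffs(f0, fs, q)
    sig <- zerophase_filter_cpp(nc$b, nc$a, sig)
  }
  restore_signal(x, sig)
}

#' Segment a movement into overlapping analysis windows
#'
#' Drops the initial reaction phase (default 0.25 s), then slides a 500 ms
#' window in 125 ms steps (75% overlap) over the remainder; windows that
#' would extend past the movement end are dropped. A 1 s movement yields
#' exactly three windows, starting at 0.25, 0.375 and 0.5 s. Each window is
#' restricted to the region's 64 channels in raster order and carries full
#' provenance.
#'
#' @param recording An `emg_recording` (signal samples x 256 channels).
#' @param region A [select_region()] selection.
#' @param trim,win,step Segmentation parameters, seconds.
#' @return List of `window_segment`s: `data` (window samples x 64),
#'   `window_index` (0-based), `start_time`, and `provenance`.
#' @export
segment_windows <- function(recording, region, trim = 0.25, win = 0.5,
                            step = 0.125) {
  fs <- recording$fs
  n <- nrow(recording$signal)
  dur <- n / fs
  if (dur < trim + win) {
    stop(sprintf("movement too short to segment: %.3f s < trim %.3f + window %.3f",
                 dur, trim, win))
  }
  wlen <- round(win * fs)
  starts <- numeric(0)
  k <- 0
  while (trim + k * step + win <= dur + 1e-9) {
    starts <- c(starts, trim + k * step)
    k <- k + 1
  }
  lapply(seq_along(starts), function(i) {
    i0 <- round(starts[i] * fs) + 1
    structure(list(
      data = recording$signal[i0:(i0 + wlen - 1), region$channels,
                              drop = FALSE],
      window_index = i - 1L,
      start_time = starts[i],
      provenance = c(recording$meta, list(region_id = region$region_id))),
      class = "window_segment")
  })
}
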