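#' Feature thresholds
#'
#' Detection thresholds for the amplitude-gated features, in post-amplifier
#' units: myopulse percentage rate and Willison amplitude at 0.05 V, slope
#' sign change at 4e-5 (product of successive slopes, V^2).
#'
#' @param myop_thr,wamp_thr Volts.
#' @param ssc_thr Squared volts.
#' @return `feature_thresholds` list.
#' @export
feature_thresholds <- function(myop_thr = 0.05, wamp_thr = 0.05,
                               ssc_thr = 0.00004) {
  stopifnot(myop_thr >= 0, wamp_thr >= 0, ssc_thr >= 0)
  structure(list(myop_thr = myop_thr, wamp_thr = wamp_thr,
                 ssc_thr = ssc_thr), class = "feature_thresholds")
}

#' Canonical feature order
#' @return Character vector of the eight per-channel feature names.
#' @export
feature_order <- function() {
  c("RMS", "SSC", "MYOP", "Skew", "WAMP", "Kurt", "MNF", "MDF")
}

#' Root mean square amplitude
#' @param x Numeric sample vector.
#' @return `sqrt(mean(x^2))`.
#' @export
emg_rms <- function(x) {
  if (length(x) < 1) stop("empty window")
  sqrt(mean(x^2))
}

#' Slope sign change count
#'
#' Counts interior samples where the signal slope reverses with sufficient
#' amplitude: `(x[i] - x[i-1]) * (x[i] - x[i+1]) >= thr`.
#'
#' @param x Numeric sample vector (length >= 3).
#' @param thr Threshold on the slope product (V^2).
#' @return Integer count.
#' @export
emg_ssc <- function(x, thr = 0.00004) {
  n <- length(x)
  if (n < 3) stop("SSC needs at least 3 samples")
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  sum(d1 * d2 >= thr)
}

#' Myopulse percentage rate
#'
#' Fraction of samples whose absolute amplitude reaches the threshold.
#'
#' @param x Numeric sample vector.
#' @param thr Amplitude threshold, V.
#' @return Fraction in \[0, 1\].
#' @export
emg_myop <- function(x, thr = 0.05) {
  if (length(x) < 1) stop("empty window")
  mean(abs(x) >= thr)
}

#' Willison amplitude
#'
#' Number of successive-sample differences whose magnitude reaches the
#' threshold.
#'
#' @param x Numeric sample vector (length >= 2).
#' @param thr Amplitude threshold, V.
#' @return Integer count.
#' @export
emg_wamp <- function(x, thr = 0.05) {
  if (length(x) < 2) stop("WAMP needs at least 2 samples")
  sum(abs(diff(x)) >= thr)
}

#' Sample skewness (third standardized moment)
#'
#' Population-style (uncorrected) moments; zero-variance windows return 0.
#'
#' @param x Numeric sample vector.
#' @return Dimensionless skewness.
#' @export
emg_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Sample kurtosis (fourth standardized moment, non-excess)
#'
#' Gaussian data converge to 3. Population-style moments; zero-variance
#' windows return 0.
#'
#' @param x Numeric sample vector.
#' @return Dimensionless kurtosis.
#' @export
emg_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2
}

# Hann-tapered periodogram restricted to the analysis band; returns
# frequencies and per-channel power columns
band_periodogram <- function(X, fs, band) {
  n <- nrow(X)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  P <- Mod(stats::mvfft(X * w))^2
  half <- seq_len(floor(n / 2) + 1)
  f <- fs * (half - 1) / n
  keep <- f >= band[1] & f <= band[2]
  list(f = f[keep], P = P[half, , drop = FALSE][keep, , drop = FALSE])
}

#' Mean frequency of the power spectrum
#'
#' Power-weighted mean frequency of the Hann-tapered periodogram,
#' restricted to the analysis band (default: the 10-500 Hz pipeline
#' pass-band). All-zero windows return 0.
#'
#' @param x Numeric sample vector (length >= 8).
#' @param fs Sampling rate, Hz.
#' @param band Analysis band, Hz.
#' @return Mean frequency, Hz.
#' @export
emg_mnf <- function(x, fs, band = c(10, 500)) {
  if (length(x) < 8) stop("MNF needs at least 8 samples")
  pg <- band_periodogram(matrix(x, ncol = 1), fs, band)
  tot <- sum(pg$P)
  if (tot <= 0) return(0)
  sum(pg$f * pg$P) / tot
}

#' Median frequency of the power spectrum
#'
#' Smallest frequency at which cumulative band power reaches half the total
#' band power (same estimator and band as [emg_mnf()]).
#'
#' @inheritParams emg_mnf
#' @return Median frequency, Hz.
#' @export
emg_mdf <- function(x, fs, band = c(10, 500)) {
  if (length(x) < 8) stop("MDF needs at least 8 samples")
  pg <- band_periodogram(matrix(x, ncol = 1), fs, band)
  tot <- sum(pg$P)
  if (tot <= 0) return(0)
  pg$f[which.max(cumsum(pg$P[, 1]) >= tot / 2)]
}

#' Per-channel feature matrix of one window
#'
#' Computes the eight features for every channel of a window at once
#' (vectorized across channels).
#'
#' @param X Window data, samples x channels matrix.
#' @param fs Sampling rate, Hz.
#' @param thresholds A [feature_thresholds()].
#' @param band Spectral analysis band, Hz.
#' @return channels x 8 matrix, columns in [feature_order()].
#' @export
window_features <- function(X, fs, thresholds = feature_thresholds(),
                            band = c(10, 500)) {
  n <- nrow(X)
  if (n < 8) stop("window too short")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  m2 <- colMeans(Xc^2)
  rms <- sqrt(colMeans(X^2))
  myop <- colMeans(abs(X) >= thresholds$myop_thr)
  wamp <- colSums(abs(diff(X)) >= thresholds$wamp_thr)
  d1 <- X[2:(n - 1), , drop = FALSE] - X[1:(n - 2), , drop = FALSE]
  d2 <- X[2:(n - 1), , drop = FALSE] - X[3:n, , drop = FALSE]
  ssc <- colSums(d1 * d2 >= thresholds$ssc_thr)
  skew <- ifelse(m2 > 0, colMeans(Xc^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, colMeans(Xc^4) / m2^2, 0)
  pg <- band_periodogram(X, fs, band)
  tot <- colSums(pg$P)
  mnf <- ifelse(tot > 0, colSums(pg$P * pg$f) / tot, 0)
  cum <- apply(pg$P, 2, cumsum)
  mdf <- vapply(seq_along(tot), function(j) {
    if (tot[j] <= 0) return(0)
    pg$f[which.max(cum[, j] >= tot[j] / 2)]
  }, numeric(1))
  out <- cbind(RMS = rms, SSC = ssc, MYOP = myop, Skew = skew,
               WAMP = wamp, Kurt = kurt, MNF = mnf, MDF = mdf)
  rownames(out) <- NULL
  out
}

#' Assemble the 512-length feature vector of a window
#'
#' Channel-major ordering: for each of the 64 region channels (raster
#' order), the eight features in [feature_order()]. Length is always
#' 64 x 8 = 512.
#'
#' @param segment A `window_segment` (64 channels), or a samples x 64
#'   matrix.
#' @param fs Sampling rate (taken from provenance-free matrices).
#' @param thresholds A [feature_thresholds()].
#' @param repair Apply spatial outlier repair to each 16 x 4 feature map
#'   before flattening.
#' @return Named numeric vector of length 512 (`ch001_RMS`, ...).
#' @export
extract_vector <- function(segment, fs = 2048,
                           thresholds = feature_thresholds(),
                           repair = TRUE) {
  X <- if (inherits(segment, "window_segment")) segment$data else segment
  if (ncol(X) != 64) stop("feature vector requires exactly 64 channels")
  F <- window_features(X, fs, thresholds)
  if (repair) F <- repair_feature_maps(F)
  v <- as.vector(t(F))
  names(v) <- paste0("ch", sprintf("%03d", rep(1:64, each = 8)), "_",
                     rep(feature_order(), times = 64))
  v
}

#' Windowed feature table for a dataset and region
#'
#' Runs the per-recording front end of the pipeline: restrict to the
#' region's 64 channels, band-pass (10-500 Hz) and notch-comb filter,
#' segment into overlapping windows, extract the 512-length feature vector
#' per window (with spatial outlier repair by default).
#'
#' @param dataset An `emg_dataset`.
#' @param region A [select_region()] selection.
#' @param thresholds A [feature_thresholds()].
#' @param repair Enable feature-map outlier repair.
#' @param trim,win,step Segmentation parameters, seconds.
#' @return An `emg_features` object: list with `meta` (one row per window:
#'   subject, day, gesture, trial, movement, window_index, movement_id),
#'   `X` (windows x 512 matrix) and `region_id`.
#' @export
feature_table <- function(dataset, region,
                          thresholds = feature_thresholds(),
                          repair = TRUE, trim = 0.25, win = 0.5,
                          step = 0.125) {
  fs <- dataset$config$fs
  rows <- list()
  vecs <- list()
  for (rec in dataset$recordings) {
    rsig <- rec$signal[, region$channels, drop = FALSE]
    rsig <- bandpass(rsig, fs)
    rsig <- notch_comb(rsig, fs)
    sub <- structure(list(signal = rsig, fs = fs, meta = rec$meta),
                     class = "emg_recording")
    ident <- structure(list(region_id = region$region_id,
                            channels = seq_len(64)),
                       class = "region_selection")
    for (seg in segment_windows(sub, ident, trim, win, step)) {
      vecs[[length(vecs) + 1]] <-
        extract_vector(seg$data, fs, thresholds, repair = repair)
      m <- rec$meta
      rows[[length(rows) + 1]] <- data.frame(
        subject = m$subject, day = m$day, gesture = m$gesture,
        trial = m$trial, movement = m$movement,
        window_index = seg$window_index, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  meta$movement_id <- paste(meta$subject, meta$day, meta$gesture, meta$trial,
                            meta$movement, sep = "/")
  structure(list(meta = meta, X = do.call(rbind, vecs),
                 region_id = region$region_id),
            class = "emg_features")
}
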