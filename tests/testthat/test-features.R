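test_that("closed-form feature values on tiny fixtures", {
  expect_equal(emg_rms(c(3, -4)), sqrt(12.5))
  expect_equal(emg_rms(rep(-2, 5)), 2)
  expect_equal(emg_rms(rep(0, 4)), 0)

  expect_equal(emg_ssc(c(1, 2, 3, 4), thr = 0), 0)  # monotone
  expect_equal(emg_ssc(c(0, 1, 0, 1, 0), thr = 0.5), 3)
  expect_equal(emg_ssc(rnorm(50), thr = Inf), 0)

  expect_equal(emg_myop(rep(0.1, 10), thr = 0.05), 1)
  expect_equal(emg_myop(rep(0, 10), thr = 0.05), 0)
  expect_equal(emg_myop(c(0.06, 0.04, 0.06, 0.04), thr = 0.05), 0.5)

  expect_equal(emg_wamp(rep(0.3, 6), thr = 0.05), 0)
  expect_equal(emg_wamp(c(0, 0.1, 0, 0.1), thr = 0.05), 3)
  x <- rnorm(100)
  expect_equal(emg_wamp(x, thr = 0), 99)

  expect_equal(emg_skewness(c(-1, 0, 1)), 0)
  expect_equal(emg_kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(emg_skewness(rep(2, 8)), 0)  # zero-variance guard
  expect_equal(emg_kurtosis(rep(2, 8)), 0)
})

test_that("kurtosis of a large Gaussian sample converges to 3", {
  set.seed(404)
  expect_equal(emg_kurtosis(rnorm(1e5)), 3, tolerance = 0.1 / 3)
})

test_that("thresholded features match brute-force enumeration on random windows", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(8:32, 1)
    x <- round(rnorm(n, 0, 0.08), 3)
    thr_a <- sample(c(0, 0.02, 0.05, 0.1), 1)
    thr_s <- sample(c(0, 4e-5, 1e-3), 1)
    expect_identical(emg_ssc(x, thr_s), oracle_ssc(x, thr_s))
    expect_identical(emg_myop(x, thr_a), oracle_myop(x, thr_a))
    expect_identical(emg_wamp(x, thr_a), oracle_wamp(x, thr_a))
  }
})

test_that("scale behaviour: RMS 1-homogeneous, moments scale-free, thresholds monotone", {
  set.seed(12)
  x <- rnorm(256, 0, 0.1)
  expect_equal(emg_rms(3 * x), 3 * emg_rms(x))
  expect_equal(emg_skewness(5 * x), emg_skewness(x))
  expect_equal(emg_kurtosis(5 * x), emg_kurtosis(x))
  thrs <- c(0, 0.01, 0.05, 0.2, 1)
  for (f in list(emg_myop, emg_wamp, emg_ssc)) {
    vals <- vapply(thrs, function(th) as.numeric(f(x, th)), numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("spectral features: pure and mixed tones, band containment", {
  fs <- 2048
  t <- (0:1023) / fs
  tone <- sin(2 * pi * 100 * t)
  expect_equal(emg_mnf(tone, fs), 100, tolerance = 2 / 100)
  expect_equal(emg_mdf(tone, fs), 100, tolerance = 2 / 100)
  two <- sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
  expect_equal(emg_mnf(two, fs), 100, tolerance = 2 / 100)
  set.seed(3)
  x <- rnorm(1024)
  for (v in c(emg_mnf(x, fs), emg_mdf(x, fs))) {
    expect_gte(v, 10)
    expect_lte(v, 500)
  }
  expect_equal(emg_mnf(rep(0, 1024), fs), 0)  # degenerate guard
})

test_that("extract_vector produces a deterministic 512-length channel-major vector", {
  set.seed(21)
  X <- matrix(rnorm(1024 * 64, 0, 0.05), 1024, 64)
  v1 <- extract_vector(X, repair = FALSE)
  v2 <- extract_vector(X, repair = FALSE)
  expect_length(v1, 512)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  # channel-major blocks: permuting channels permutes 8-long blocks
  perm <- sample(64)
  vp <- extract_vector(X[, perm], repair = FALSE)
  blocks <- function(v) lapply(1:64, function(c) unname(v[(c - 1) * 8 + 1:8]))
  expect_equal(blocks(vp), blocks(v1)[perm])
  # per-channel block equals the single-channel features
  ch <- X[, 17]
  expect_equal(unname(v1[(17 - 1) * 8 + 1:8]),
               c(emg_rms(ch), emg_ssc(ch, 4e-5), emg_myop(ch, 0.05),
                 emg_skewness(ch), emg_wamp(ch, 0.05), emg_kurtosis(ch),
                 emg_mnf(ch, 2048), emg_mdf(ch, 2048)))
  expect_error(extract_vector(X[, 1:10]), "64 channels")
})
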