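# small configs and independent oracles shared across test files

tiny_config <- function(...) {
  defaults <- list(n_subjects = 1, n_days = 1, n_gestures = 3, n_trials = 1,
                   snr_db = 20, p_bad_channel = 0, seed = 123)
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# direct-enumeration oracles for the thresholded features
oracle_ssc <- function(x, thr) {
  cnt <- 0L
  for (i in 2:(length(x) - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= thr) cnt <- cnt + 1L
  }
  cnt
}

oracle_myop <- function(x, thr) {
  cnt <- 0L
  for (i in seq_along(x)) if (abs(x[i]) >= thr) cnt <- cnt + 1L
  cnt / length(x)
}

oracle_wamp <- function(x, thr) {
  cnt <- 0L
  for (i in seq_len(length(x) - 1)) {
    if (abs(x[i + 1] - x[i]) >= thr) cnt <- cnt + 1L
  }
  cnt
}

# nearest-valid-neighbour reconstruction by exhaustive grid-distance search
oracle_reconstruct <- function(map, mask) {
  out <- map
  for (r in seq_len(nrow(map))) {
    for (c in seq_len(ncol(map))) {
      if (!mask[r, c]) next
      best_d <- Inf
      vals <- numeric(0)
      for (rr in seq_len(nrow(map))) {
        for (cc in seq_len(ncol(map))) {
          if (mask[rr, cc]) next
          d <- sqrt((rr - r)^2 + (cc - c)^2)
          if (d < best_d - 1e-12) {
            best_d <- d
            vals <- map[rr, cc]
          } else if (abs(d - best_d) <= 1e-12) {
            vals <- c(vals, map[rr, cc])
          }
        }
      }
      out[r, c] <- mean(vals)
    }
  }
  out
}

# exact two-sided signed-rank p by enumeration over all sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(statistic = v_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Friedman chi-square from explicit within-row ranks
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  colsum <- colSums(R)
  12 / (n * k * (k + 1)) * sum(colsum^2) - 3 * n * (k + 1)
}
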