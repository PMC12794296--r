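#' Friedman repeated-measures test across regions
#'
#' Nonparametric omnibus test of whether the matched per-subject accuracy
#' columns (one per electrode region) share a common location, based on
#' within-subject ranks (ties receive mean ranks). Used instead of
#' parametric repeated-measures ANOVA because accuracies are bounded and
#' non-normal.
#'
#' @param accuracy_matrix Numeric matrix, subjects x regions (>= 2 of each),
#'   no missing cells.
#' @return List with `statistic` (Friedman chi-square), `df` and `p.value`.
#' @details The plain mean-rank chi-square statistic
#' \eqn{\chi^2 = 12/(nk(k+1)) \sum_j R_j^2 - 3n(k+1)} is used (ties receive
#' mean ranks, no tie-correction factor), so fully tied data give statistic
#' 0 and p = 1 rather than an undefined ratio.
#' @export
friedman_test <- function(accuracy_matrix) {
  m <- as.matrix(accuracy_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 regions")
  if (anyNA(m)) stop("accuracy matrix contains missing cells")
  n <- nrow(m)
  k <- ncol(m)
  R <- t(apply(m, 1, rank))
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  list(statistic = stat, df = k - 1,
       p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Two-sided signed-rank test on the paired differences `a - b`, zero
#' differences excluded before ranking. The exact null distribution is used
#' for small samples: by sign enumeration for up to 12 non-zero differences
#' (valid under tied magnitudes), by the signed-rank distribution for
#' untied magnitudes up to 25; otherwise the normal approximation with
#' continuity correction. The Bonferroni-adjusted p-value multiplies by the
#' number of pairwise comparisons performed (default 3, one per region
#' pair).
#'
#' @param a,b Paired accuracy vectors of equal length.
#' @param m_comparisons Bonferroni multiplier.
#' @return List with `statistic` (V, rank sum of positive differences),
#'   `p_raw`, `p_adjusted` and `n_effective` (non-zero differences).
#' @export
wilcoxon_bonferroni <- function(a, b, m_comparisons = 3) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_raw = 1, p_adjusted = 1,
                n_effective = 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12) {
    # exact two-sided p by enumeration over all 2^n sign assignments,
    # valid with tied magnitudes (mean ranks)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    p <- min(1, 2 * min(mean(v_all <= v), mean(v_all >= v)))
  } else {
    exact <- n <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided",
                                       exact = exact, correct = TRUE))
    p <- wt$p.value
  }
  list(statistic = v, p_raw = p,
       p_adjusted = min(1, m_comparisons * p),
       n_effective = n)
}

#' Region-wise statistical comparison
#'
#' Friedman omnibus test across the region columns followed by all pairwise
#' Wilcoxon signed-rank tests with Bonferroni correction (m = number of
#' pairs). Significance threshold: p <= 0.05.
#'
#' @param accuracy_matrix Subjects x regions matrix with column names.
#' @return List with `friedman` and a `pairwise` data frame.
#' @export
compare_regions <- function(accuracy_matrix) {
  m <- as.matrix(accuracy_matrix)
  fr <- friedman_test(m)
  pairs <- utils::combn(ncol(m), 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    ci <- pairs[1, i]; cj <- pairs[2, i]
    w <- wilcoxon_bonferroni(m[, ci], m[, cj], m_comparisons = n_pairs)
    data.frame(region_a = colnames(m)[ci], region_b = colnames(m)[cj],
               statistic = w$statistic, p_raw = w$p_raw,
               p_adjusted = w$p_adjusted, n_effective = w$n_effective)
  }))
  list(friedman = fr, pairwise = pw)
}
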