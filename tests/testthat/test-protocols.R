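# metadata-only window table mirroring the acquisition schedule
make_meta <- function(n_subjects = 2, n_days = 2, gestures = c("g1", "g2"),
                      n_trials = 1, n_movements = 3, n_windows = 3) {
  cfg <- expand.grid(window_index = seq_len(n_windows) - 1L,
                     movement = seq_len(n_movements),
                     trial = seq_len(n_trials), gesture = gestures,
                     day = seq_len(n_days), subject = seq_len(n_subjects),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cfg$movement_id <- paste(cfg$subject, cfg$day, cfg$gesture, cfg$trial,
                           cfg$movement, sep = "/")
  cfg
}

test_that("leave-one-movement-out folds partition a subject-day's windows", {
  meta <- make_meta(n_subjects = 1, n_days = 1, gestures = c("a", "b", "c"),
                    n_trials = 2)
  folds <- intra_subject_folds(meta, 1, 1)
  expect_length(folds, 3 * 2 * 3)  # gestures x trials x movements
  for (f in folds) expect_length(f$test, 3)  # the 3 windows of one movement
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, seq_len(nrow(meta)))  # each window tested once
  expect_true(audit_folds(folds, meta))
  expect_error(intra_subject_folds(meta, 5, 1), "no windows")
})

test_that("inter-day split separates days strictly, one per subject", {
  meta <- make_meta(n_subjects = 3)
  for (s in 1:3) {
    f <- inter_day_split(meta, s)
    expect_true(all(meta$day[f$train] == 1))
    expect_true(all(meta$day[f$test] == 2))
    expect_length(intersect(f$train, f$test), 0)
    expect_true(audit_folds(list(f), meta))
  }
  meta1 <- make_meta(n_days = 1)
  expect_error(inter_day_split(meta1, 1), "missing a recording day")
})

test_that("leave-one-subject-out folds are subject-disjoint on day 1", {
  meta <- make_meta(n_subjects = 4)
  folds <- inter_subject_folds(meta)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(unique(meta$subject[f$test]), 1)
    expect_length(unique(meta$subject[f$train]), 3)
    expect_true(all(meta$day[c(f$train, f$test)] == 1))
  }
  expect_true(audit_folds(folds, meta))
  expect_error(inter_subject_folds(make_meta(n_subjects = 1)), ">= 2 subjects")
})

test_that("the leakage audit catches contaminated folds", {
  meta <- make_meta()
  good <- inter_subject_folds(meta)
  bad <- good
  bad[[1]]$train <- c(bad[[1]]$train, bad[[1]]$test[1])
  expect_error(audit_folds(bad, meta), "both partitions|share window")
  bad2 <- intra_subject_folds(meta, 1, 1)
  # move one window of the held-out movement into training
  bad2[[1]]$train <- c(bad2[[1]]$train, bad2[[1]]$test[1])
  bad2[[1]]$test <- bad2[[1]]$test[-1]
  expect_error(audit_folds(bad2, meta), "movement")
})

test_that("run_protocol aggregates per subject and pools confusion counts", {
  cfg <- tiny_config(n_subjects = 2, n_days = 2, n_gestures = 3,
                     n_trials = 1, snr_db = 20, seed = 31)
  ds <- generate_dataset(cfg)
  ft <- feature_table(ds, select_region(build_layout(), "distal_wrist"))
  res <- run_protocol(ft, "intra_subject", seed = 2)
  expect_s3_class(res, "protocol_result")
  expect_length(res$per_subject, 2)
  expect_equal(res$accuracy, mean(res$per_subject))
  # per-subject score = mean over days of mean over that day's folds
  pf <- res$per_fold
  s1 <- mean(vapply(1:2, function(d) {
    mean(pf$accuracy[pf$subject == 1 & pf$day == d])
  }, numeric(1)))
  expect_equal(unname(res$per_subject["1"]), s1)
  # pooled confusion counts = total test windows
  expect_equal(sum(res$confusion), sum(pf$n_test))
  rd <- run_protocol(ft, "inter_day", seed = 2)
  expect_equal(nrow(rd$per_fold), 2)
  rs <- run_protocol(ft, "inter_subject", seed = 2)
  expect_equal(nrow(rs$per_fold), 2)
  # reruns with the same seed reproduce exactly
  expect_equal(run_protocol(ft, "inter_day", seed = 2)$accuracy, rd$accuracy)
})

test_that("Friedman wrapper matches hand-ranked oracle and handles ties", {
  m <- matrix(c(0.95, 0.90, 0.85,
                0.92, 0.91, 0.80,
                0.99, 0.95, 0.90), 3, 3, byrow = TRUE)
  fr <- friedman_test(m)
  expect_equal(fr$statistic, oracle_friedman(m))
  expect_equal(fr$df, 2)
  # agrees with the reference implementation on untied data
  ref <- stats::friedman.test(m)
  expect_equal(fr$statistic, unname(ref$statistic))
  expect_equal(fr$p.value, ref$p.value)
  # identical columns: statistic 0, p = 1
  same <- matrix(rep(c(0.8, 0.9, 0.7), 3), 3, 3)
  fr0 <- friedman_test(same)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p.value, 1)
  # column permutation leaves the statistic unchanged
  expect_equal(friedman_test(m[, c(3, 1, 2)])$statistic, fr$statistic)
  expect_error(friedman_test(m[1, , drop = FALSE]), ">= 2 subjects")
  m_na <- m; m_na[2, 2] <- NA
  expect_error(friedman_test(m_na), "missing")
})

test_that("Wilcoxon signed-rank matches exact enumeration and Bonferroni scales p", {
  a <- c(0.91, 0.85, 0.88, 0.93, 0.81, 0.90)
  b <- c(0.86, 0.86, 0.80, 0.85, 0.83, 0.82)
  w <- wilcoxon_bonferroni(a, b, m_comparisons = 3)
  oe <- oracle_signed_rank(a - b)
  expect_equal(unname(w$statistic), oe$statistic)
  expect_equal(w$p_raw, oe$p)
  expect_equal(w$p_adjusted, min(1, 3 * oe$p))
  # equal vectors are degenerate: p = 1
  wd <- wilcoxon_bonferroni(a, a)
  expect_equal(wd$p_adjusted, 1)
  expect_equal(wd$n_effective, 0)
  # Bonferroni is plain multiplication, capped at 1
  expect_equal(wilcoxon_bonferroni(a, b, m_comparisons = 50)$p_adjusted,
               min(1, 50 * oe$p))
  # untied magnitudes: agrees with the reference exact implementation
  a2 <- c(0.91, 0.85, 0.88, 0.93, 0.81, 0.90)
  b2 <- c(0.87, 0.86, 0.80, 0.86, 0.84, 0.84)
  ref <- wilcox.test(a2, b2, paired = TRUE, exact = TRUE)
  w2 <- wilcoxon_bonferroni(a2, b2)
  expect_equal(unname(w2$statistic), unname(ref$statistic))
  expect_equal(w2$p_raw, ref$p.value)
})

test_that("compare_regions reports the omnibus test plus 3 corrected pairs", {
  set.seed(17)
  m <- cbind(distal = runif(8, 0.9, 1), mid = runif(8, 0.7, 0.9),
             proximal = runif(8, 0.5, 0.7))
  cr <- compare_regions(m)
  expect_equal(nrow(cr$pairwise), 3)
  expect_true(all(cr$pairwise$p_adjusted >= cr$pairwise$p_raw))
  expect_true(all(cr$pairwise$p_adjusted <= 1))
  expect_lt(cr$friedman$p.value, 0.05)
})
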