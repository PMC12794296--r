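fold_spec <- function(protocol, train, test, fold_index, context = list()) {
  structure(list(protocol = protocol, train = train, test = test,
                 fold_index = fold_index, context = context),
            class = "fold_spec")
}

#' Leave-one-movement-out folds for one subject-day
#'
#' One fold per gesture movement: the held-out movement's windows (all
#' three overlapping segments) form the test set; every other movement of
#' the same subject and day trains. Windows of one movement are never split
#' across partitions, preventing temporal leakage from overlapping windows.
#'
#' @param meta Window metadata (the `meta` component of an `emg_features`).
#' @param subject,day Context selectors.
#' @return List of `fold_spec`s (indices into `meta` rows).
#' @export
intra_subject_folds <- function(meta, subject, day) {
  rows <- which(meta$subject == subject & meta$day == day)
  if (length(rows) == 0) stop("no windows for subject ", subject, " day ", day)
  movements <- unique(meta$movement_id[rows])
  lapply(seq_along(movements), function(i) {
    test <- rows[meta$movement_id[rows] == movements[i]]
    fold_spec("intra_subject", setdiff(rows, test), test, i,
              list(subject = subject, day = day, movement_id = movements[i]))
  })
}

#' Inter-day split for one subject
#'
#' All day-1 windows train, all day-2 windows test; strict temporal
#' separation, one fold per subject.
#'
#' @param meta Window metadata.
#' @param subject Subject id.
#' @param train_day,test_day Day indices.
#' @return A single `fold_spec`.
#' @export
inter_day_split <- function(meta, subject, train_day = 1, test_day = 2) {
  train <- which(meta$subject == subject & meta$day == train_day)
  test <- which(meta$subject == subject & meta$day == test_day)
  if (length(train) == 0 || length(test) == 0) {
    stop("subject ", subject, " is missing a recording day")
  }
  fold_spec("inter_day", train, test, 1, list(subject = subject))
}

#' Leave-one-subject-out folds (day 1 only)
#'
#' One fold per subject: the held-out subject's day-1 windows test, the
#' remaining subjects' day-1 windows train. No subject contributes to both
#' partitions of any fold.
#'
#' @param meta Window metadata.
#' @param day Day used for both partitions (default 1).
#' @return List of `fold_spec`s.
#' @export
inter_subject_folds <- function(meta, day = 1) {
  subjects <- sort(unique(meta$subject))
  if (length(subjects) < 2) stop("inter-subject validation needs >= 2 subjects")
  lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    test <- which(meta$subject == s & meta$day == day)
    train <- which(meta$subject != s & meta$day == day)
    fold_spec("inter_subject", train, test, i, list(subject = s))
  })
}

#' Audit folds for train/test leakage
#'
#' Verifies, for every fold, that train and test indices are disjoint, that
#' no gesture movement contributes windows to both partitions, and (for
#' inter-subject folds) that no subject appears on both sides.
#'
#' @param folds List of `fold_spec`s.
#' @param meta Window metadata the indices refer to.
#' @return `TRUE` invisibly; stops on any violation.
#' @export
audit_folds <- function(folds, meta) {
  for (f in folds) {
    if (length(intersect(f$train, f$test)) > 0) {
      stop("fold ", f$fold_index, ": train and test share window indices")
    }
    shared <- intersect(meta$movement_id[f$train], meta$movement_id[f$test])
    if (length(shared) > 0) {
      stop("fold ", f$fold_index, ": movement(s) span both partitions: ",
           paste(shared, collapse = ", "))
    }
    if (f$protocol == "inter_subject") {
      if (length(intersect(meta$subject[f$train],
                           meta$subject[f$test])) > 0) {
        stop("fold ", f$fold_index, ": subject appears in both partitions")
      }
    }
  }
  invisible(TRUE)
}

# fit the fold-local reduce + classify chain and score the test partition
run_fold <- function(X, y, f, svm_cfg, var_target, hyper = NULL,
                     classes = NULL) {
  scaler <- fit_scaler(X[f$train, , drop = FALSE])
  Ztr <- apply_scaler(scaler, X[f$train, , drop = FALSE])
  proj <- suppressWarnings(fit_pca(Ztr, var_target))
  Str <- apply_pca(proj, Ztr)
  Ste <- apply_pca(proj, apply_scaler(scaler, X[f$test, , drop = FALSE]))
  ytr <- y[f$train]
  if (is.null(hyper)) {
    gs <- grid_search(Str, ytr, svm_cfg)
    hyper <- list(C = gs$C, gamma = gs$gamma)
  }
  model <- svm_train(Str, ytr, svm_cfg, C = hyper$C, gamma = hyper$gamma)
  if (is.null(classes)) classes <- model$classes
  ev <- svm_evaluate(model, Ste, y[f$test], classes = classes)
  list(accuracy = ev$accuracy, confusion = ev$confusion, D = proj$D,
       C = hyper$C, gamma = hyper$gamma, n_test = length(f$test),
       hyper = hyper)
}

#' Run a validation protocol end to end
#'
#' Builds the protocol's folds over the precomputed windowed features,
#' audits each fold for leakage, and for every fold fits the fold-local
#' z-score scaler, variance-constrained PCA and one-vs-all SVM (with grid
#' search) on the training partition only, then scores the held-out
#' partition. Aggregation: intra-subject folds are averaged within each
#' subject-day, then across days, giving one score per subject; the other
#' protocols yield one score per subject directly.
#'
#' @param features An [feature_table()] result.
#' @param protocol `"intra_subject"`, `"inter_day"` or `"inter_subject"`.
#' @param svm_cfg An [svm_config()].
#' @param var_target PCA explained-variance target.
#' @param hyper_mode `"per_fold"` re-runs the grid search in every fold;
#'   `"shared"` runs it once per subject-day context (intra-subject) and
#'   reuses the pair, trading fidelity for speed.
#' @param seed Seed for validation splits (combined with fold context).
#' @return A `protocol_result`: `protocol`, `region_id`, `per_fold` data
#'   frame, `per_subject` named accuracy vector, overall `accuracy`
#'   (mean of per-subject scores) and pooled `confusion` counts.
#' @export
run_protocol <- function(features, protocol = c("intra_subject", "inter_day",
                                                "inter_subject"),
                         svm_cfg = svm_config(), var_target = 0.95,
                         hyper_mode = c("per_fold", "shared"), seed = 1L) {
  protocol <- match.arg(protocol)
  hyper_mode <- match.arg(hyper_mode)
  meta <- features$meta
  X <- features$X
  y_all <- meta$gesture
  classes <- sort(unique(y_all))
  subjects <- sort(unique(meta$subject))
  per_fold <- list()
  confusion <- NULL
  add <- function(rec, f) {
    per_fold[[length(per_fold) + 1]] <<- data.frame(
      subject = f$context$subject,
      day = if (!is.null(f$context$day)) f$context$day else NA_integer_,
      fold_index = f$fold_index, accuracy = rec$accuracy, D = rec$D,
      C = rec$C, gamma = rec$gamma, n_test = rec$n_test)
    confusion <<- if (is.null(confusion)) rec$confusion
                  else confusion + rec$confusion
  }
  if (protocol == "intra_subject") {
    for (s in subjects) {
      for (d in sort(unique(meta$day[meta$subject == s]))) {
        folds <- intra_subject_folds(meta, s, d)
        audit_folds(folds, meta)
        hyper <- NULL
        for (f in folds) {
          cfg <- svm_cfg
          cfg$seed <- mix_seed(seed, s, d, f$fold_index)
          rec <- run_fold(X, y_all, f, cfg, var_target,
                          hyper = if (hyper_mode == "shared") hyper,
                          classes = classes)
          if (hyper_mode == "shared" && is.null(hyper)) hyper <- rec$hyper
          add(rec, f)
        }
      }
    }
  } else if (protocol == "inter_day") {
    for (s in subjects) {
      f <- inter_day_split(meta, s)
      audit_folds(list(f), meta)
      cfg <- svm_cfg
      cfg$seed <- mix_seed(seed, s, 19)
      add(run_fold(X, y_all, f, cfg, var_target, classes = classes), f)
    }
  } else {
    folds <- inter_subject_folds(meta)
    audit_folds(folds, meta)
    for (f in folds) {
      cfg <- svm_cfg
      cfg$seed <- mix_seed(seed, f$fold_index, 23)
      add(run_fold(X, y_all, f, cfg, var_target, classes = classes), f)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  if (protocol == "intra_subject") {
    by_day <- aggregate(accuracy ~ subject + day, per_fold, mean)
    by_subj <- aggregate(accuracy ~ subject, by_day, mean)
  } else {
    by_subj <- aggregate(accuracy ~ subject, per_fold, mean)
  }
  per_subject <- setNames(by_subj$accuracy, by_subj$subject)
  structure(list(protocol = protocol, region_id = features$region_id,
                 per_fold = per_fold, per_subject = per_subject,
                 accuracy = mean(per_subject), confusion = confusion),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<%s protocol, region %s>\n", x$protocol, x$region_id))
  cat(sprintf("  mean accuracy: %.4f over %d subjects (%d folds)\n",
              x$accuracy, length(x$per_subject), nrow(x$per_fold)))
  invisible(x)
}

#' Row-normalize a pooled confusion matrix
#' @param confusion Counts matrix (rows = true labels).
#' @return Row-stochastic matrix (rows with no samples stay zero).
#' @export
normalize_confusion <- function(confusion) {
  rs <- rowSums(confusion)
  rs[rs == 0] <- 1
  confusion / rs
}
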