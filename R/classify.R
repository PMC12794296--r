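#' SVM configuration
#'
#' Hyperparameter search space and validation-split settings for the
#' one-vs-all SVM: C in \{0.1, 1, 10\} and gamma in \{0.01, 0.1, 1\},
#' selected by accuracy on a stratified 10% holdout of the training set.
#' With the default linear kernel gamma does not enter the decision
#' function; the full 3 x 3 grid is evaluated regardless, and an `rbf`
#' kernel option makes gamma live.
#'
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param C_grid,gamma_grid Numeric grids.
#' @param val_fraction Validation fraction of the training set, in (0, 0.5].
#' @param seed Seed for the stratified split.
#' @return An `svm_config` list.
#' @export
svm_config <- function(kernel = c("linear", "radial"),
                       C_grid = c(0.1, 1, 10),
                       gamma_grid = c(0.01, 0.1, 1),
                       val_fraction = 0.10, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(length(C_grid) >= 1, length(gamma_grid) >= 1,
            val_fraction > 0, val_fraction <= 0.5)
  structure(list(kernel = kernel, C_grid = sort(C_grid),
                 gamma_grid = sort(gamma_grid),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "svm_config")
}

# fit K binary one-vs-all learners; decision sign oriented so that larger
# values favour the target class
fit_ova <- function(X, y, C, gamma, kernel) {
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training set must contain >= 2 classes")
  learners <- lapply(classes, function(k) {
    yf <- factor(ifelse(y == k, "target", "rest"),
                 levels = c("target", "rest"))
    m <- e1071::svm(x = X, y = yf, kernel = kernel, cost = C, gamma = gamma,
                    scale = FALSE)
    dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")[, 1]
    sign <- if (mean(dv[y == k]) >= mean(dv[y != k])) 1 else -1
    list(model = m, sign = sign)
  })
  structure(list(learners = learners, classes = classes, C = C,
                 gamma = gamma, kernel = kernel),
            class = "ova_svm")
}

ova_decision_values <- function(model, X) {
  dv <- vapply(model$learners, function(l) {
    l$sign *
      attr(predict(l$model, X, decision.values = TRUE),
           "decision.values")[, 1]
  }, numeric(nrow(X)))
  matrix(dv, nrow = nrow(X),
         dimnames = list(NULL, model$classes))
}

# stratified validation holdout: at least one sample per class
stratified_holdout <- function(y, fraction, seed) {
  set.seed(seed)
  val <- integer(0)
  for (k in sort(unique(y))) {
    idx <- which(y == k)
    n_val <- max(1L, round(fraction * length(idx)))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    if (n_val >= 1) val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Hyperparameter grid search
#'
#' Evaluates every (C, gamma) pair of the grid by fitting the one-vs-all
#' model on 90% of the training set and scoring accuracy on a stratified,
#' seeded 10% validation holdout. Ties are broken towards smaller C, then
#' smaller gamma.
#'
#' @param X,y Training features and labels.
#' @param config An [svm_config()].
#' @return List with `C`, `gamma`, and the full `scores` matrix
#'   (C x gamma validation accuracies).
#' @export
grid_search <- function(X, y, config = svm_config()) {
  if (length(unique(y)) < 2) stop("training set must contain >= 2 classes")
  val <- stratified_holdout(y, config$val_fraction, config$seed)
  trn <- setdiff(seq_along(y), val)
  scores <- matrix(NA_real_, length(config$C_grid),
                   length(config$gamma_grid),
                   dimnames = list(C = config$C_grid,
                                   gamma = config$gamma_grid))
  best <- list(acc = -Inf, C = config$C_grid[1], gamma = config$gamma_grid[1])
  for (ci in seq_along(config$C_grid)) {
    for (gi in seq_along(config$gamma_grid)) {
      m <- fit_ova(X[trn, , drop = FALSE], y[trn],
                   config$C_grid[ci], config$gamma_grid[gi], config$kernel)
      acc <- mean(svm_predict(m, X[val, , drop = FALSE]) == y[val])
      scores[ci, gi] <- acc
      if (acc > best$acc + 1e-12) {
        best <- list(acc = acc, C = config$C_grid[ci],
                     gamma = config$gamma_grid[gi])
      }
    }
  }
  list(C = best$C, gamma = best$gamma, scores = scores)
}

#' Train a one-vs-all SVM
#'
#' Runs the grid search (unless fixed hyperparameters are supplied), then
#' refits one binary learner per class on the full training set. Prediction
#' is by maximum decision value, ties broken by class order.
#'
#' @param X,y Training features and labels.
#' @param config An [svm_config()].
#' @param C,gamma Optional fixed hyperparameters (skip the grid search).
#' @return An `ova_svm` model.
#' @export
svm_train <- function(X, y, config = svm_config(), C = NULL, gamma = NULL) {
  if (is.null(C) || is.null(gamma)) {
    gs <- grid_search(X, y, config)
    C <- gs$C
    gamma <- gs$gamma
  }
  fit_ova(X, y, C, gamma, config$kernel)
}

#' Predict gesture labels
#' @param model An `ova_svm`.
#' @param X Feature matrix.
#' @return Character vector of predicted labels.
#' @export
svm_predict <- function(model, X) {
  dv <- ova_decision_values(model, X)
  model$classes[max.col(dv, ties.method = "first")]
}

#' Evaluate a model on labelled data
#'
#' @param model An `ova_svm`.
#' @param X,y Test features and labels.
#' @param classes Label universe for the confusion matrix (defaults to the
#'   model's classes).
#' @return List with `accuracy` and `confusion` (rows = true labels,
#'   raw counts; normalize rows for reporting).
#' @export
svm_evaluate <- function(model, X, y, classes = model$classes) {
  pred <- svm_predict(model, X)
  cm <- table(factor(y, levels = classes), factor(pred, levels = classes))
  list(accuracy = mean(pred == y),
       confusion = unclass(as.matrix(cm)))
}
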