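#' Confusion-matrix summary metrics
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts.
#' @return Tibble with `accuracy`, `sensitivity`, `specificity` and the
#'   counts.
#' @export
#' @examples
#' confusion_metrics(tp = 2, fp = 0, tn = 3, fn = 1)
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    validation_error("confusion counts must be non-negative integers.")
  }
  if (sum(counts) == 0) param_error("confusion counts are all zero.")
  tibble(
    accuracy = (tp + tn) / sum(counts),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Leave-one-out cross-validated SVM classification
#'
#' Discriminates two groups from nodal network features (typically
#' betweenness AUC at the implicated regions). Each subject is predicted by a
#' support vector machine trained on all other subjects; features are
#' z-scored with means and SDs estimated on the training fold only, so no
#' information leaks from the held-out subject.
#'
#' @param features data frame with a label column and numeric feature columns
#'   (a `subject_id` column, if present, is carried through to the fold
#'   table).
#' @param label label column (bare name or string), two classes.
#' @param positive which class counts as a positive call (sensitivity refers
#'   to it); defaults to the second factor level, e.g. the patient or
#'   melancholic class.
#' @param kernel,cost,gamma SVM hyperparameters passed to [e1071::svm()];
#'   `gamma` defaults to `1 / n_features`.
#' @param seed RNG seed (the fit itself is deterministic; the seed guards
#'   library internals).
#' @return Object of class `svm_loocv`: confusion counts, `accuracy`,
#'   `sensitivity`, `specificity`, per-fold predictions, and settings.
#' @export
#' @examples
#' f <- tibble::tibble(x1 = c(rnorm(10, 0), rnorm(10, 6)),
#'                     x2 = rnorm(20), label = rep(c("a", "b"), each = 10))
#' loocv_svm(f, label)
loocv_svm <- function(features, label = "label", positive = NULL,
                      kernel = "radial", cost = 1, gamma = NULL, seed = 1L) {
  features <- as_tibble(features)
  label <- resolve_col(features, {{ label }})
  y <- droplevels(as.factor(features[[label]]))
  if (nlevels(y) != 2) param_error("classification requires exactly 2 classes.")
  if (any(table(y) < 2)) param_error("each class needs at least 2 subjects.")
  ids <- if ("subject_id" %in% names(features)) features$subject_id else
    paste0("s", seq_len(nrow(features)))
  X <- as.matrix(features[setdiff(names(features), c(label, "subject_id"))])
  if (!is.numeric(X) || anyNA(X)) validation_error("features must be numeric and complete.")
  positive <- positive %||% levels(y)[2]
  if (!positive %in% levels(y)) param_error("`positive` must be one of the class labels.")
  gamma <- gamma %||% (1 / ncol(X))
  n <- nrow(X)
  pred <- character(n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      Zte <- (X[i, ] - mu) / sdv
      fit <- e1071::svm(Ztr, y[tr], kernel = kernel, cost = cost,
                        gamma = gamma, scale = FALSE)
      pred[i] <- as.character(stats::predict(fit, matrix(Zte, nrow = 1)))
    }
  })
  truth <- as.character(y)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  cm <- confusion_metrics(tp, fp, tn, fn)
  structure(
    list(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
         specificity = cm$specificity,
         tp = tp, fp = fp, tn = tn, fn = fn,
         folds = tibble(subject_id = ids, truth = truth, predicted = pred,
                        correct = truth == pred),
         positive = positive, kernel = kernel, cost = cost, gamma = gamma,
         seed = seed, n = n, features = colnames(X)),
    class = "svm_loocv")
}

#' @export
print.svm_loocv <- function(x, ...) {
  cat(sprintf(
    "<svm_loocv> n = %d | accuracy %.1f%% (%d/%d), sensitivity %.1f%%, specificity %.1f%% (positive: %s)\n",
    x$n, 100 * x$accuracy, x$tp + x$tn, x$n, 100 * x$sensitivity,
    100 * x$specificity, x$positive))
  invisible(x)
}
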