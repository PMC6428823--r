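#' Stratified train/test split
#'
#' Splits a labeled dataset at `train_fraction`, preserving the class
#' balance within rounding: each class contributes
#' `round(n_class * train_fraction)` training samples. Deterministic for a
#' fixed seed. A balanced 1572-sample set at 0.7 yields the 1100/472
#' partition with 236 test samples per class.
#'
#' @param data a [labeled_dataset()].
#' @param train_fraction in (0, 1), default 0.7.
#' @param seed RNG seed.
#' @return list with `train` and `test` datasets.
#' @export
split_dataset <- function(data, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in unique(data$labels)) {
    idx <- which(data$labels == cl)
    n_tr <- round(length(idx) * train_fraction)
    if (n_tr == 0L || n_tr == length(idx)) {
      stop("split would leave an empty partition for class ", cl,
           call. = FALSE)
    }
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  test_idx <- setdiff(seq_along(data$labels), train_idx)
  list(train = subset_dataset(data, sort(train_idx)),
       test = subset_dataset(data, sort(test_idx)))
}

#' Confusion matrix with nodule as the positive class
#'
#' @param pred_labels,true_labels equal-length character vectors with
#'   values `nodule`/`non_nodule`.
#' @return list of class `confusion_matrix` with integer `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) == 0L || length(pred_labels) != length(true_labels)) {
    stop("label vectors must be nonempty and of equal length", call. = FALSE)
  }
  pos <- true_labels == "nodule"
  ppos <- pred_labels == "nodule"
  confusion_matrix(tp = sum(pos & ppos), fp = sum(!pos & ppos),
                   fn = sum(pos & !ppos), tn = sum(!pos & !ppos))
}

#' @rdname confusion
#' @param tp,fp,fn,tn nonnegative counts (for building a matrix directly,
#'   e.g. from a published table).
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  structure(lapply(as.list(counts), as.integer),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d FN=%d TN=%d>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' * accuracy    = (TP + TN) / (TP + FP + TN + FN) x 100
#' * sensitivity = TP / (TP + FN) x 100 (true-positive rate)
#' * specificity = TN / (TN + FP) x 100 (true-negative rate)
#'
#' `printed_eq12 = TRUE` switches sensitivity to the nonstandard
#' TP / (TP + FP) variant (i.e. precision) that occasionally appears in
#' print; the default is the standard definition, which is what reported
#' nodule-detection results follow.
#'
#' Zero denominators yield `NaN` for the affected metric rather than an
#' error. Values are returned unrounded; see [round_half_up()] for the
#' 2-decimal reporting convention.
#'
#' @param cm a `confusion_matrix`.
#' @param printed_eq12 use the precision-style sensitivity variant.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   in percent.
#' @examples
#' metrics(confusion_matrix(233, 2, 3, 234))
#' @export
metrics <- function(cm, printed_eq12 = FALSE) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  sens_den <- if (printed_eq12) cm$tp + cm$fp else cm$tp + cm$fn
  c(accuracy = if (total > 0) 100 * (cm$tp + cm$tn) / total else NaN,
    sensitivity = if (sens_den > 0) 100 * cm$tp / sens_den else NaN,
    specificity = if (cm$tn + cm$fp > 0) 100 * cm$tn / (cm$tn + cm$fp) else NaN)
}

#' Round half away from zero
#'
#' Reporting convention for percentages: round half up to `digits`
#' decimals (base R `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places, default 2.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Samples of each class are dealt round-robin (after seeded shuffling)
#' into k folds, so fold sizes differ by at most one and every sample is
#' tested exactly once. Each fold is scored with [metrics()] against the
#' model trained on the remaining folds.
#'
#' @param data a [labeled_dataset()].
#' @param k folds, `2 <= k <=` minority class size.
#' @param seed RNG seed (fold assignment and solver).
#' @param ... passed to [train_svm()].
#' @return list with `per_fold` (k x 3 matrix), `mean`, `sd`.
#' @export
kfold_cv <- function(data, k = 5L, seed = 1L, ...) {
  stopifnot(inherits(data, "labeled_dataset"))
  k <- as.integer(k)
  min_class <- min(table(data$labels))
  if (k < 2L || k > min_class) {
    stop("k must be in [2, minority class size]", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  fold <- integer(length(data$labels))
  for (cl in unique(data$labels)) {
    idx <- sample(which(data$labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  per_fold <- matrix(NA_real_, k, 3,
                     dimnames = list(NULL, c("accuracy", "sensitivity",
                                             "specificity")))
  for (f in seq_len(k)) {
    tr <- subset_dataset(data, which(fold != f))
    te <- subset_dataset(data, which(fold == f))
    model <- train_svm(tr, seed = seed, ...)
    pred <- predict(model, te)
    per_fold[f, ] <- metrics(confusion(pred$labels, te$labels))
  }
  list(per_fold = per_fold,
       mean = colMeans(per_fold),
       sd = apply(per_fold, 2L, stats::sd),
       fold_sizes = tabulate(fold, k))
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the unique scores (classifying
#' `score >= t` as nodule) and returns the (FPR, TPR) pairs, anchored at
#' (0, 0) and (1, 1) and ordered by FPR; the curve is monotone by
#' construction. Also reports the area under the curve by trapezoidal
#' integration.
#'
#' @param scores numeric decision scores (higher = more nodule-like).
#' @param true_labels character vector of `nodule`/`non_nodule`.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_points <- function(scores, true_labels) {
  pos <- true_labels == "nodule"
  if (!any(pos) || all(pos)) {
    stop("need at least one sample of each class", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
  # collapse ties on score: keep the last point of each tied run
  keep <- c(diff(scores[o]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(pos))
  fpr <- c(0, fp[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
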