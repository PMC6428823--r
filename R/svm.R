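#' Labeled candidate dataset
#'
#' Container pairing an N x M feature matrix with N labels in
#' `{"nodule", "non_nodule"}` and provenance ids. All classifier and
#' protocol functions consume this.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels character/factor vector, values `nodule`/`non_nodule`.
#' @param ids optional provenance keys, default row numbers.
#' @return list of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, ids = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("row count must equal label count", call. = FALSE)
  }
  if (anyNA(features) || anyNA(labels)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("nodule", "non_nodule"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(features = features, labels = labels,
                 ids = ids %||% seq_len(nrow(features))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d samples x %d features (%d nodule / %d non_nodule)>\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == "nodule"), sum(x$labels == "non_nodule")))
  invisible(x)
}

subset_dataset <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  data$ids[idx])
}

#' Train a soft-margin kernel SVM
#'
#' Fits the maximum-margin classifier by solving the dual problem with a
#' sequential-minimal-optimization solver (see `src/smo.cpp`). Features
#' are z-scored with training-set statistics only (stored in the model and
#' reapplied at prediction, so no test-set leakage). Default kernel is
#' radial basis function with `gamma = 1 / (M * mean feature variance)`
#' computed on the standardized training matrix — a robust default for
#' ~100-dimensional histogram features.
#'
#' @param train a [labeled_dataset()] with both classes present.
#' @param kernel `"rbf"` or `"linear"`.
#' @param C box constraint, default 1.
#' @param gamma RBF width; `NULL`/`NA` (default) uses the scale heuristic.
#' @param seed RNG seed for the solver's randomized sweeps.
#' @return object of class `svm_model`.
#' @export
train_svm <- function(train, kernel = c("rbf", "linear"), C = 1,
                      gamma = NULL, seed = 1L) {
  stopifnot(inherits(train, "labeled_dataset"))
  kernel <- match.arg(kernel)
  y <- ifelse(train$labels == "nodule", 1, -1)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- train$features
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  if (is.null(gamma) || is.na(gamma)) {
    v <- mean(apply(Xs, 2L, stats::var))
    gamma <- 1 / (ncol(Xs) * max(v, .Machine$double.eps))
  }
  Kmat <- kernel_matrix(Xs, Xs, kernel, gamma)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  fit <- smo_train(Kmat, y, C = C)

  sv <- which(fit$alpha > 1e-8)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 center = center, scale = scale,
                 sv_x = Xs[sv, , drop = FALSE],
                 sv_coef = fit$alpha[sv] * y[sv],
                 b = fit$b,
                 n_sv = length(sv),
                 levels = c(positive = "nodule", negative = "non_nodule")),
            class = "svm_model")
}

kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  # squared distances via the expansion ||a||^2 + ||b||^2 - 2 a.b
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model: %s kernel, C=%g, gamma=%g, %d support vectors>\n",
              x$kernel, x$C, x$gamma, x$n_sv))
  invisible(x)
}

#' Predict nodule/non-nodule labels and decision scores
#'
#' @param object an `svm_model`.
#' @param features numeric matrix (or `labeled_dataset`) with the model's
#'   feature dimension.
#' @param ... unused.
#' @return list with `labels` (character) and `scores` (signed distance
#'   proxy; positive = nodule side of the hyperplane).
#' @export
predict.svm_model <- function(object, features, ...) {
  if (inherits(features, "labeled_dataset")) features <- features$features
  features <- as.matrix(features)
  if (ncol(features) != length(object$center)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  Xs <- sweep(sweep(features, 2L, object$center), 2L, object$scale, "/")
  Kmat <- kernel_matrix(Xs, object$sv_x, object$kernel, object$gamma)
  scores <- as.vector(Kmat %*% object$sv_coef) + object$b
  list(labels = ifelse(scores >= 0, "nodule", "non_nodule"),
       scores = scores)
}
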