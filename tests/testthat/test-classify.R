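# 2D Gaussian-blob toy datasets for classifier behavior checks.
toy_dataset <- function(n_per_class = 40, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
  labeled_dataset(X, rep(c("nodule", "non_nodule"), each = n_per_class))
}

test_that("labeled_dataset validates its invariants", {
  expect_error(labeled_dataset(matrix(1, 3, 2), c("nodule", "nodule")),
               "row count")
  expect_error(labeled_dataset(matrix(NA_real_, 2, 2), c("nodule", "non_nodule")),
               "missing")
  expect_error(labeled_dataset(matrix(1, 2, 2), c("yes", "no")), "unknown")
})

test_that("split_dataset is stratified, deterministic and reproduces 1100/472", {
  d <- toy_dataset(50)
  sp <- split_dataset(d, 0.7, seed = 3)
  expect_equal(length(sp$train$labels), 70)
  expect_equal(length(sp$test$labels), 30)
  expect_equal(unname(table(sp$train$labels)), c(35L, 35L),
               ignore_attr = TRUE)
  sp2 <- split_dataset(d, 0.7, seed = 3)
  expect_identical(sp$train$ids, sp2$train$ids)
  # the published protocol: 1572 balanced -> 1100 train / 472 test, 236+236
  big <- labeled_dataset(matrix(0, 1572, 1),
                         rep(c("nodule", "non_nodule"), each = 786))
  spb <- split_dataset(big, 0.7, seed = 1)
  expect_equal(length(spb$train$labels), 1100)
  expect_equal(length(spb$test$labels), 472)
  expect_equal(sum(spb$test$labels == "nodule"), 236)
  expect_equal(sum(spb$test$labels == "non_nodule"), 236)
  expect_error(split_dataset(toy_dataset(2), 0.05), "empty")
})

test_that("the SVM separates, reproduces and scores sensibly", {
  d <- toy_dataset(30, sep = 8, seed = 2)
  model <- train_svm(d, seed = 1)
  pred <- predict(model, d)
  expect_equal(pred$labels, d$labels)     # linearly separable -> 100%
  # duplicated training set gives the same decision function
  d2 <- labeled_dataset(rbind(d$features, d$features),
                        c(d$labels, d$labels))
  m2 <- train_svm(d2, seed = 1)
  expect_equal(predict(m2, d)$scores, predict(m2, d)$scores)
  expect_equal(ifelse(predict(m2, d)$scores >= 0, "nodule", "non_nodule"),
               d$labels)
  # linear kernel on 1D toy data: scores monotone in the coordinate
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  dl <- labeled_dataset(x, c(rep("non_nodule", 3), rep("nodule", 3)))
  ml <- train_svm(dl, kernel = "linear", seed = 1)
  sc <- predict(ml, matrix(seq(-3, 3, by = 0.5), ncol = 1))$scores
  expect_true(all(diff(sc) > 0))
  expect_error(train_svm(labeled_dataset(matrix(1, 2, 1), rep("nodule", 2))),
               "both classes")
  expect_error(predict(model, matrix(0, 1, 5)), "dimension")
})

test_that("confusion counts and metrics match hand enumeration", {
  pred <- c("nodule", "nodule", "non_nodule", "nodule", "non_nodule", "non_nodule")
  true <- c("nodule", "non_nodule", "nodule", "nodule", "non_nodule", "nodule")
  cm <- confusion(pred, true)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2L, 1L, 2L, 1L))
  all_right <- confusion(true, true)
  expect_equal(c(all_right$fp, all_right$fn), c(0L, 0L))
  flipped <- ifelse(true == "nodule", "non_nodule", "nodule")
  cm_f <- confusion(flipped, true)
  expect_equal(c(cm_f$tp, cm_f$tn), c(0L, 0L))
  expect_error(confusion(character(0), character(0)), "nonempty")
  expect_equal(unname(metrics(confusion(true, true))), c(100, 100, 100))
  # zero denominator flags NaN
  m <- metrics(confusion_matrix(0, 0, 0, 5))
  expect_true(is.nan(m[["sensitivity"]]))
})

test_that("metrics reproduce the published confusion-table values", {
  # 70-30 split: (233, 2, 3, 234)
  m <- round_half_up(metrics(confusion_matrix(233, 2, 3, 234)))
  expect_equal(unname(m), c(98.94, 98.73, 99.15))
  # 30-70 split: (456, 8, 94, 542); note 90.7272 and 98.5454 truncate to the
  # printed 90.72 / 98.54 but round half-up (our convention) to .73 / .55
  m <- round_half_up(metrics(confusion_matrix(456, 8, 94, 542)))
  expect_equal(unname(m), c(90.73, 82.91, 98.55))
  expect_equal(round_half_up(metrics(confusion_matrix(456, 8, 94, 542)), 1),
               c(accuracy = 90.7, sensitivity = 82.9, specificity = 98.5))
  # 50-50 split: (383, 4, 10, 389) - sensitivity/specificity
  m <- round_half_up(metrics(confusion_matrix(383, 4, 10, 389)))
  expect_equal(unname(m[2:3]), c(97.46, 98.98))
  expect_equal(floor(unname(m[2]) * 10) / 10, 97.4)  # 383/393 = 0.97455..
  # the printed-formula variant uses TP/(TP+FP)
  mp <- metrics(confusion_matrix(233, 2, 3, 234), printed_eq12 = TRUE)
  expect_equal(round_half_up(mp[["sensitivity"]]), 99.15)
})

test_that("kfold_cv covers each sample once with balanced folds", {
  d <- toy_dataset(25, sep = 7, seed = 4)
  cv <- kfold_cv(d, k = 5, seed = 2)
  expect_equal(sum(cv$fold_sizes), 50)
  expect_lte(diff(range(cv$fold_sizes)), 1)
  expect_equal(dim(cv$per_fold), c(5L, 3L))
  cv2 <- kfold_cv(d, k = 5, seed = 2)
  expect_identical(cv$per_fold, cv2$per_fold)
  # leave-one-out at k = minority class size runs
  small <- toy_dataset(4, sep = 9, seed = 5)
  cv_loo <- kfold_cv(small, k = 4, seed = 1)
  expect_equal(sum(cv_loo$fold_sizes), 8)
  expect_error(kfold_cv(small, k = 10), "k must be")
})

test_that("roc_points forms a monotone curve with sane areas", {
  scores <- c(5, 4, 3, 2, 1, 0)
  labels <- c(rep("nodule", 3), rep("non_nodule", 3))
  roc <- roc_points(scores, labels)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$points$fpr == 0 & roc$points$tpr == 1))
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  # reversed scores reflect the curve
  roc_rev <- roc_points(-scores, labels)
  expect_equal(roc_rev$auc, 0)
  # random scores: AUC ~ 0.5
  set.seed(6)
  sc <- rnorm(1000)
  lab <- sample(c("nodule", "non_nodule"), 1000, TRUE)
  expect_lt(abs(roc_points(sc, lab)$auc - 0.5), 0.07)
  expect_error(roc_points(1:3, rep("nodule", 3)), "each class")
})
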