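test_that("max-CI aggregation selects the most confident repeat", {
  a <- aggregate_max_ci(c(1, 2, 1), c(0.5, 0.9, 0.7))
  expect_equal(a$score, 2)
  expect_equal(a$ci, 0.9)
  expect_equal(aggregate_max_ci(3, 0.4)$score, 3)
  # ties go to the lowest repeat index
  t1 <- aggregate_max_ci(c(0, 3, 1), c(0.8, 0.8, 0.3))
  expect_equal(t1$score, 0)
  expect_equal(t1$repeat_index, 1)
  expect_error(aggregate_max_ci(numeric(0), numeric(0)), "empty-input")
})

test_that("CI-weighted aggregation matches the worked example", {
  expect_equal(aggregate_weighted(c(0, 1, 1), c(0.5, 0.9, 0.8)), 1L)  # 0.7727
  expect_equal(aggregate_weighted(c(2, 2, 2), c(0.1, 0.9, 0.4)), 2L)
  expect_equal(aggregate_weighted(c(1, 2, 3), c(0.6, 0.6, 0.6)), 2L)
  # the literal (unnormalized) sum is clamped into the score range
  expect_equal(aggregate_weighted(c(3, 3, 3), c(0.9, 0.9, 0.9),
                                  normalize = FALSE), 3L)
  expect_error(aggregate_weighted(c(1, 2), c(0, 0)), "undefined-aggregate")
})

test_that("rounding is half away from zero", {
  expect_equal(aggregate_weighted(c(1, 2), c(0.5, 0.5)), 2L)  # 1.5 -> 2
  expect_equal(aggregate_weighted(c(0, 1), c(0.5, 0.5)), 1L)  # 0.5 -> 1
})

test_that("consistency is the modal fraction", {
  expect_equal(consistency(c(2, 2, 3)), 2 / 3)
  expect_equal(consistency(c(1, 1, 1)), 1.0)
  expect_equal(consistency(c(0, 1, 2)), 1 / 3)
})

test_that("aggregation properties hold over random repeat sets", {
  for (i in 1:50) {
    set.seed(i)
    n <- sample(1:3, 1)
    scores <- sample(0:3, n, replace = TRUE)
    cis <- stats::runif(n, 0.05, 1)
    expect_true(aggregate_max_ci(scores, cis)$score %in% scores)
    w <- aggregate_weighted(scores, cis)
    expect_true(w >= min(scores) && w <= max(scores))
    # binarize commutes with aggregation on unanimous repeats
    u <- rep(sample(0:3, 1), 3)
    expect_equal(binarize(aggregate_weighted(u, cis[c(1, 1, 1)])),
                 aggregate_weighted(binarize(u), cis[c(1, 1, 1)],
                                    n_classes = 2L))
  }
})

test_that("threshold curves exclude low-confidence cores monotonically", {
  scores <- c(rep(0, 10), rep(1, 10))
  labels <- c(rep(0, 10), rep(0, 10))        # the high-CI half is wrong
  cis <- c(stats::runif(10, 0.3, 0.4), stats::runif(10, 0.8, 0.9))
  cv <- threshold_curve(scores, cis, labels)
  expect_equal(cv$indeterminate_frac[cv$theta == 0], 0)
  expect_true(all(diff(cv$indeterminate_frac) >= 0))
  expect_true(is.na(cv$accuracy[cv$theta == 1]))
  # accuracy flips when the threshold crosses the separating CI
  expect_equal(cv$accuracy[cv$theta == 0.1], 0.5)
  expect_equal(cv$accuracy[cv$theta == 0.5], 0.0)
  # constructed fixture where high CI = correct
  labels2 <- c(rep(9, 10), rep(1, 10))       # low-CI half all wrong
  cv2 <- threshold_curve(scores, cis, labels2)
  expect_gt(cv2$accuracy[cv2$theta == 0.5], cv2$accuracy[cv2$theta == 0])
})

test_that("threshold_at_indeterminate returns the smallest adequate theta", {
  cis <- c(rep(0.4, 15), rep(0.9, 85))
  scores <- rep(1, 100); labels <- rep(1, 100)
  cv <- threshold_curve(scores, cis, labels)
  th <- threshold_at_indeterminate(cv, 0.15)
  expect_gt(th, 0.4)
  expect_lt(th, 0.42)
  expect_equal(threshold_at_indeterminate(cv, 0), 0)
  expect_error(threshold_at_indeterminate(cv, 1.01), "unreachable-target")
})

test_that("binarize merges 0/1+ against 2+/3+", {
  expect_equal(binarize(0:3), c(0L, 0L, 1L, 1L))
  expect_error(binarize(4), "invalid-score")
})

test_that("confusion matrices and 2-class metrics", {
  cm <- confusion_and_metrics(c(0, 1, 2, 3), c(0, 1, 2, 3), K = 4)
  expect_equal(cm$accuracy, 1.0)
  expect_true(all(cm$matrix[row(cm$matrix) != col(cm$matrix)] == 0))
  # TP=3 FN=1 TN=5 FP=1
  pred <- c(rep(1, 3), 0, rep(0, 5), 1)
  truth <- c(rep(1, 4), rep(0, 6))
  m2 <- confusion_and_metrics(pred, truth, K = 2)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 5 / 6, tolerance = 1e-12)
  expect_error(confusion_and_metrics(c(0, 1), c(0, 1, 1), K = 2), "shape error")
})

test_that("ROC/AUC handles separation, null data and ties", {
  sep <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$auc, 1.0)
  # label-independent probabilities give AUC ~ 0.5
  set.seed(123)
  p <- stats::runif(2000)
  y <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(p, y)$auc - 0.5), 0.05)
  # all-tied probabilities: exactly 0.5 by the simultaneous-step convention
  expect_equal(roc_auc(rep(0.7, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(stats::runif(5), rep(1, 5)), "undefined-AUC")
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(qlogis(p), y)$auc, roc_auc(p, y)$auc)
})

test_that("aggregate_predictions reduces a predictions table per scheme", {
  preds <- data.frame(
    core_id = rep(c("a", "b"), each = 3),
    repeat_index = rep(1:3, 2),
    score = c(1, 2, 1, 3, 3, 0),
    ci = c(0.5, 0.9, 0.7, 0.6, 0.8, 0.3))
  expect_equal(nrow(aggregate_predictions(preds, "3N")), 6)
  mx <- aggregate_predictions(preds, "maxci")
  expect_equal(mx$score[mx$core_id == "a"], 2)
  expect_equal(mx$ci[mx$core_id == "b"], 0.8)
  wt <- aggregate_predictions(preds, "weighted")
  expect_equal(wt$score[wt$core_id == "a"],
               aggregate_weighted(c(1, 2, 1), c(0.5, 0.9, 0.7)))
})
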