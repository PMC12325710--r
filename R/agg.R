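# Repeat-scan aggregation and evaluation: three confidence schemes
# (3N / max-CI / CI-weighted), mode consistency, CI-threshold curves with
# indeterminate rates, confusion matrices and 2-class ROC/AUC.

#' Max-CI aggregation of repeat predictions
#'
#' Selects the repeat with the highest confidence; ties go to the lowest
#' repeat index.
#'
#' @param scores per-repeat predicted scores.
#' @param cis per-repeat confidence values.
#' @param repeats repeat indices (default 1..n); used for ordering and the
#'   tie rule.
#' @return list with `score`, `ci`, `repeat_index`.
#' @export
aggregate_max_ci <- function(scores, cis, repeats = seq_along(scores)) {
  if (length(scores) == 0L)
    stop("empty-input: no repeats to aggregate", call. = FALSE)
  stopifnot(length(scores) == length(cis), length(repeats) == length(scores))
  ord <- order(repeats)
  scores <- scores[ord]; cis <- cis[ord]; repeats <- repeats[ord]
  i <- which.max(cis)  # first maximum = lowest repeat index
  list(score = scores[i], ci = cis[i], repeat_index = repeats[i])
}

# round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' CI-weighted aggregation of repeat predictions
#'
#' Multiplies each score by its confidence, sums, and rounds. The primary
#' form divides by the summed confidence (a weighted mean), which keeps the
#' result inside the score range; `normalize = FALSE` gives the literal
#' weighted sum. Rounding is half away from zero and the result is clamped
#' to `0 .. n_classes-1`.
#'
#' @param scores per-repeat predicted scores.
#' @param cis per-repeat confidence values (sum must be positive).
#' @param normalize divide by `sum(cis)` (default TRUE).
#' @param n_classes score range for clamping.
#' @return aggregated integer score.
#' @export
aggregate_weighted <- function(scores, cis, normalize = TRUE, n_classes = 4L) {
  if (length(scores) == 0L)
    stop("empty-input: no repeats to aggregate", call. = FALSE)
  stopifnot(length(scores) == length(cis))
  if (sum(cis) <= 0)
    stop("undefined-aggregate: all confidence values are zero", call. = FALSE)
  val <- sum(scores * cis) / if (normalize) sum(cis) else 1
  as.integer(min(max(round_half_away(val), 0), n_classes - 1L))
}

#' Mode consistency of repeat predictions
#'
#' Fraction of repeats equal to the most frequent prediction (the mode).
#' When all values are distinct each is a mode; the lowest score is reported
#' and the proportion is `1/n`.
#'
#' @param scores per-repeat predicted scores.
#' @return fraction in (0, 1].
#' @export
consistency <- function(scores) {
  if (length(scores) == 0L)
    stop("empty-input: no repeats", call. = FALSE)
  tab <- table(scores)
  max(tab) / length(scores)
}

#' Aggregate a predictions table per core
#'
#' @param preds data.frame with `core_id`, `repeat_index`, `score`, `ci`.
#' @param method `"3N"` keeps every scan as its own row; `"maxci"` and
#'   `"weighted"` reduce each core to one row. Under the weighted scheme the
#'   reported CI is the CI-weighted mean of the repeat CIs.
#' @return data.frame with `core_id`, `score`, `ci` (plus `repeat_index` for
#'   `"3N"`).
#' @export
aggregate_predictions <- function(preds, method = c("3N", "maxci", "weighted")) {
  method <- match.arg(method)
  if (method == "3N")
    return(preds[, intersect(c("core_id", "repeat_index", "score", "ci"),
                             names(preds))])
  parts <- split(preds, preds$core_id)
  rows <- lapply(parts, function(p) {
    p <- p[order(p$repeat_index), ]
    if (method == "maxci") {
      a <- aggregate_max_ci(p$score, p$ci, p$repeat_index)
      data.frame(core_id = p$core_id[1], score = a$score, ci = a$ci,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(core_id = p$core_id[1],
                 score = aggregate_weighted(p$score, p$ci),
                 ci = sum(p$ci * p$ci) / sum(p$ci), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy / indeterminate-rate threshold curve
#'
#' For each confidence threshold, predictions with CI below the threshold
#' are marked indeterminate; accuracy is computed over the determinate rest
#' (and reported as `NA` when everything is excluded).
#'
#' @param scores predicted scores.
#' @param cis confidence values.
#' @param labels true scores.
#' @param thresholds threshold grid (default 101 points on \[0, 1\]).
#' @return data.frame of class `threshold_curve`: `theta`, `accuracy`,
#'   `indeterminate_frac`.
#' @export
threshold_curve <- function(scores, cis, labels,
                            thresholds = seq(0, 1, length.out = 101L)) {
  if (length(scores) == 0L)
    stop("empty-input: no predictions", call. = FALSE)
  stopifnot(length(scores) == length(cis), length(scores) == length(labels))
  rows <- lapply(thresholds, function(th) {
    det <- cis >= th
    data.frame(theta = th,
               accuracy = if (any(det)) mean(scores[det] == labels[det]) else NA_real_,
               indeterminate_frac = mean(!det))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Threshold achieving a target indeterminate rate
#'
#' Smallest grid threshold whose indeterminate fraction reaches the target
#' (e.g. 0.15 for a 15% indeterminate rate).
#'
#' @param curve `threshold_curve`.
#' @param target_fraction target indeterminate fraction.
#' @return threshold value.
#' @export
threshold_at_indeterminate <- function(curve, target_fraction) {
  stopifnot(nrow(curve) > 0)
  ok <- which(curve$indeterminate_frac >= target_fraction)
  if (length(ok) == 0L)
    stop("unreachable-target: no threshold reaches the target rate", call. = FALSE)
  min(curve$theta[ok])
}

#' Merge 4-class scores into the 2-class grouping
#'
#' Scores 0 and 1+ map to 0 (HER2-negative group), 2+ and 3+ to 1
#' (HER2-positive group).
#'
#' @param score_4class scores in `{0, 1, 2, 3}`.
#' @return scores in `{0, 1}`.
#' @export
binarize <- function(score_4class) {
  if (any(!score_4class %in% 0:3))
    stop("invalid-score: scores must be in {0,1,2,3}", call. = FALSE)
  as.integer(score_4class >= 2L)
}

#' Confusion matrix and summary metrics
#'
#' @param pred predicted classes `0 .. K-1`.
#' @param truth true classes.
#' @param K number of classes.
#' @return list with `matrix` (rows = true, cols = predicted), `accuracy`,
#'   and for `K = 2` also `sensitivity` (class 1 = 2+/3+ positive) and
#'   `specificity`.
#' @export
confusion_and_metrics <- function(pred, truth, K = 4L) {
  if (length(pred) != length(truth))
    stop("shape error: pred and truth differ in length", call. = FALSE)
  lv <- 0:(K - 1L)
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- unclass(cm)
  dimnames(cm) <- list(true = lv, predicted = lv)
  out <- list(matrix = cm, accuracy = sum(diag(cm)) / sum(cm))
  if (K == 2L) {
    tp <- cm["1", "1"]; fn <- cm["1", "0"]
    tn <- cm["0", "0"]; fp <- cm["0", "1"]
    out$sensitivity <- tp / (tp + fn)
    out$specificity <- tn / (tn + fp)
  }
  out
}

#' ROC curve and AUC for the 2-class task
#'
#' Threshold sweep on the positive-class probability; tied probabilities
#' step simultaneously, and the AUC (trapezoid rule) equals the
#' mid-rank Mann-Whitney statistic, so it is invariant under strictly
#' monotone transforms of the probabilities.
#'
#' @param positive_probabilities probability (or any monotone score) of the
#'   positive class.
#' @param labels true binary labels (0/1); both classes must be present.
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(positive_probabilities, labels) {
  stopifnot(length(positive_probabilities) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined-AUC: both classes must be present", call. = FALSE)
  r <- rank(positive_probabilities, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(positive_probabilities), decreasing = TRUE)
  curve <- do.call(rbind, lapply(c(Inf, thr, -Inf), function(t) {
    pos <- positive_probabilities >= t
    data.frame(threshold = t, fpr = sum(pos & labels == 0L) / n0,
               tpr = sum(pos & labels == 1L) / n1)
  }))
  list(curve = curve, auc = auc)
}
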