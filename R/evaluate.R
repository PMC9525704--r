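# Evaluation metrics: K-by-K confusion matrix, one-vs-rest counts per class,
# accuracy (both the micro-averaged one-vs-rest form and the plain multiclass
# fraction correct), per-class precision/recall/F1, and one-vs-rest ROC AUC.

#' One-vs-rest metrics from confusion counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Tibble with `precision`, `recall`, `f1` and `accuracy` (in percent).
#' @export
ovr_metrics <- function(tp, fp, fn, tn) {
  precision <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
  f1 <- ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
               NA_real_, 2 * precision * recall / (precision + recall))
  tibble::tibble(
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / (tp + fn + fp + tn) * 100
  )
}

#' Evaluate a fitted classifier on one cohort partition
#'
#' Computes the confusion matrix, one-vs-rest counts per class, accuracy
#' (micro-averaged one-vs-rest, plus the plain multiclass fraction correct),
#' per-class precision/recall/F1 and one-vs-rest ROC AUC from the continuous
#' class scores. A class absent from the partition gets `NA` (not 0) AUC.
#'
#' @param model A `subtype_classifier`.
#' @param data Cohort tibble (typically one partition) with true `subtype`
#'   labels, on the scale the model was trained on.
#' @param partition_tag Label stored in the report (e.g. `"test"`).
#' @return An `eval_report` object; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
evaluate <- function(model, data, partition_tag = NA_character_) {
  stopifnot(inherits(model, "subtype_classifier"))
  .assert_cohort(data)
  classes <- model$classes
  prob <- predict(model, data, type = "prob")
  pred <- classes[max.col(prob, ties.method = "first")]
  truth <- data$subtype
  n <- length(truth)

  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  per_class <- purrr::map_dfr(classes, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    tn <- sum(truth != cls & pred != cls)
    pos <- truth == cls
    auc <- if (!any(pos) || all(pos)) NA_real_ else rank_auc(prob[, cls], pos)
    dplyr::bind_cols(tibble::tibble(class = cls, tp = tp, fp = fp, fn = fn, tn = tn),
                     ovr_metrics(tp, fp, fn, tn), tibble::tibble(auc = auc))
  })
  structure(
    list(
      confusion = confusion,
      per_class = per_class,
      accuracy = sum(per_class$tp + per_class$tn) /
        sum(per_class$tp + per_class$fn + per_class$fp + per_class$tn) * 100,
      accuracy_multiclass = mean(truth == pred) * 100,
      roc = .roc_points(prob, truth, classes),
      n = n,
      partition = partition_tag,
      model_kind = model$kind
    ),
    class = "eval_report"
  )
}

#' Rank-based one-vs-rest ROC AUC
#'
#' Mann-Whitney form: the probability that a positive sample outscores a
#' negative one (ties counted half). Agrees with trapezoidal ROC integration.
#'
#' @param score Numeric scores, higher = more positive.
#' @param positive Logical vector marking the positive class.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.roc_points <- function(prob, truth, classes) {
  purrr::map_dfr(classes, function(cls) {
    pos <- truth == cls
    if (!any(pos) || all(pos)) return(tibble::tibble())
    r <- pROC::roc(response = pos, predictor = prob[, cls],
                   direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
    tibble::tibble(class = cls, fpr = rev(1 - r$specificities),
                   tpr = rev(r$sensitivities))
  })
}

#' Per-class metric rows of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    partition = x$partition,
    model_kind = x$model_kind,
    n = x$n,
    accuracy = x$accuracy,
    accuracy_multiclass = x$accuracy_multiclass,
    macro_f1 = mean(x$per_class$f1, na.rm = TRUE),
    min_auc = suppressWarnings(min(x$per_class$auc, na.rm = TRUE))
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s partition, %d samples (%s)\n",
              x$partition, x$n, x$model_kind))
  cat(sprintf("accuracy (micro one-vs-rest): %.1f%%  | multiclass: %.1f%%\n",
              x$accuracy, x$accuracy_multiclass))
  print(x$per_class)
  invisible(x)
}
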