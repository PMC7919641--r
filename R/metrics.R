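#' Confusion matrix at a probability threshold
#'
#' Counts at `prob >= threshold` with annotated PGx as the positive class.
#' Printed in the conventional orientation (rows: predicted neutral / PGx;
#' columns: not annotated / annotated). Rows with `NA` probability
#' (abstentions) are dropped unless `count_abstentions = TRUE`, in which
#' case they are counted as predicted neutral.
#'
#' @param model a fitted `pgx_model`, or a numeric vector of probabilities.
#' @param test_matrix predictor matrix (ignored when `model` is a vector).
#' @param test_labels logical labels.
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @param count_abstentions count `NA` predictions as neutral instead of
#'   dropping them.
#' @return object of class `pgx_confusion` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
evaluate_test <- function(model, test_matrix = NULL, test_labels,
                          threshold = 0.5, count_abstentions = FALSE) {
  if (threshold <= 0 || threshold >= 1)
    stop_invalid("threshold must lie in (0, 1)")
  prob <- if (is.numeric(model)) model else predict_prob(model, test_matrix)
  if (length(prob) != length(test_labels))
    stop_invalid("labels and predictions have different lengths")
  if (anyNA(prob)) {
    if (count_abstentions) prob[is.na(prob)] <- 0
    else { keep <- !is.na(prob); prob <- prob[keep]
           test_labels <- test_labels[keep] }
  }
  pred <- prob >= threshold
  confusion_matrix(tp = sum(pred & test_labels),
                   fp = sum(pred & !test_labels),
                   tn = sum(!pred & !test_labels),
                   fn = sum(!pred & test_labels))
}

#' @rdname evaluate_test
#' @param tp,fp,tn,fn non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop_invalid("confusion counts must be non-negative")
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "pgx_confusion")
}

#' @export
print.pgx_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), nrow = 2, byrow = TRUE,
              dimnames = list(c("neutral", "PGx"),
                              c("Not annotated", "Annotated PGx")))
  cat("Prediction (rows) vs annotation (columns):\n")
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' `sens = tp/(tp+fn)`, `spec = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/(tp+fp+tn+fn)`.
#'
#' @param cm a `pgx_confusion` (or list with `tp`, `fp`, `tn`, `fn`).
#' @param method_name label carried into the result.
#' @param auc optional AUC to attach.
#' @return data.frame `method_name`, `sensitivity`, `specificity`,
#'   `accuracy`, `auc`.
#' @export
compute_metrics <- function(cm, method_name = "model", auc = NA_real_) {
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  if (pos == 0 || neg == 0)
    stop_invalid("both classes must be present to compute sens/spec")
  data.frame(method_name = method_name,
             sensitivity = cm$tp / pos,
             specificity = cm$tn / neg,
             accuracy = (cm$tp + cm$tn) / (pos + neg),
             auc = auc, stringsAsFactors = FALSE)
}

#' Area under the ROC curve by pair counting
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, ties counting one half — computed via midranks
#' (Mann-Whitney), which equals exhaustive pair counting exactly.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop(errorCondition("AUC undefined: one class absent",
                        class = c("pgx_undefined_metric", "error")))
  r <- rank(scores)  # midranks: ties count 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Metrics for comparator scoring methods
#'
#' Each comparator contributes one numeric score column, a direction
#' (whether high or low scores indicate a functional variant) and a binary
#' threshold. Rows with a missing score are excluded per method and logged
#' in the `n_used` column.
#'
#' @param score_table data.frame of per-variant scores, one column per
#'   method.
#' @param labels logical labels (annotated PGx).
#' @param thresholds named numeric thresholds, one per method.
#' @param directions named character, `"higher"` (default) if larger scores
#'   mean functional, `"lower"` otherwise.
#' @return data.frame, one row per method: `method_name`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`, `n_used`.
#' @export
comparator_metrics <- function(score_table, labels, thresholds,
                               directions = NULL) {
  methods <- names(score_table)
  rows <- lapply(methods, function(mth) {
    sc <- score_table[[mth]]
    dir <- (directions %||% setNames(rep("higher", length(methods)),
                                     methods))[[mth]]
    keep <- !is.na(sc)
    sc_k <- sc[keep]; lab_k <- labels[keep]
    if (dir == "lower") sc_k <- -sc_k
    thr <- thresholds[[mth]]
    if (dir == "lower") thr <- -thr
    pred <- sc_k >= thr
    cm <- confusion_matrix(tp = sum(pred & lab_k), fp = sum(pred & !lab_k),
                           tn = sum(!pred & !lab_k), fn = sum(!pred & lab_k))
    out <- compute_metrics(cm, method_name = mth, auc = auc(sc_k, lab_k))
    out$n_used <- sum(keep)
    out
  })
  do.call(rbind, rows)
}
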