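#' Confusion matrix over the four rhythm classes
#'
#' @param true_labels,predicted_labels Vectors of equal length with values
#'   in [rhythm_classes()].
#' @return 4x4 integer matrix, rows = true class, columns = predicted
#'   class, in the fixed class order.
#' @export
confusion_matrix_ecg <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  cls <- rhythm_classes()
  tl <- as.character(true_labels); pl <- as.character(predicted_labels)
  if (!all(tl %in% cls) || !all(pl %in% cls))
    stop("labels must be drawn from rhythm_classes()", call. = FALSE)
  cm <- table(factor(tl, levels = cls), factor(pl, levels = cls))
  m <- matrix(as.integer(cm), 4, 4, dimnames = list(true = cls,
                                                    predicted = cls))
  m
}

#' Challenge-style per-class F1 scores and accuracy
#'
#' Per-class `F1 = 2 TP / (2 TP + FP + FN)`; a class with no true and no
#' predicted members is assigned F1 = 1 (degenerate-denominator
#' convention). The overall F1 averages the Normal, AF and Other classes
#' only — the Noisy class is computed and reported but excluded, following
#' the Challenge scoring convention. Accuracy is trace / total over all
#' four classes.
#'
#' @param cm A [confusion_matrix_ecg()] result.
#' @return List with `f1` (named per-class vector), `overall_f1` and `acc`.
#' @export
challenge_scores <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  cls <- rownames(cm)
  f1 <- vapply(seq_along(cls), function(i) {
    tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
    den <- 2 * tp + fp + fn
    if (den == 0) 1 else 2 * tp / den
  }, numeric(1))
  names(f1) <- cls
  list(f1 = f1,
       overall_f1 = mean(f1[c("Normal", "AF", "Other")]),
       acc = sum(diag(cm)) / sum(cm))
}

# K-class MCC in covariance form, shared by metrics and model validation.
mcc_from_matrix <- function(cm) {
  s <- sum(cm); c0 <- sum(diag(cm))
  t <- rowSums(cm); p <- colSums(cm)
  num <- c0 * s - sum(p * t)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (!is.finite(den) || den == 0) return(0)
  num / den
}

#' Multiclass Matthews correlation coefficient
#'
#' The K-class MCC in covariance form:
#' `(c s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`,
#' where `c` is the number of correct predictions, `s` the total, and
#' `p_k`, `t_k` the predicted and true counts of class k. Degenerate
#' denominators return 0. Reduces to the classical binary MCC on a 2x2
#' table.
#'
#' @param cm A confusion matrix (counts).
#' @return Scalar in \[-1, 1\].
#' @export
multiclass_mcc <- function(cm) mcc_from_matrix(as.matrix(cm))

#' Binary AF-detection scores
#'
#' Maps the four classes to AF vs non-AF (Normal, Other and Noisy combined)
#' and scores AF as the positive class.
#'
#' @inheritParams confusion_matrix_ecg
#' @return List with `sensitivity`, `specificity`, `accuracy` (each in
#'   \[0, 1\]); a score whose denominator is empty (e.g. sensitivity with
#'   no true AF) is reported as `NA`.
#' @export
binary_af_scores <- function(true_labels, predicted_labels) {
  cls <- rhythm_classes()
  tl <- as.character(true_labels); pl <- as.character(predicted_labels)
  if (!all(tl %in% cls) || !all(pl %in% cls))
    stop("labels must be drawn from rhythm_classes()", call. = FALSE)
  tp <- sum(tl == "AF" & pl == "AF")
  fn <- sum(tl == "AF" & pl != "AF")
  tn <- sum(tl != "AF" & pl != "AF")
  fp <- sum(tl != "AF" & pl == "AF")
  list(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       accuracy = (tp + tn) / length(tl))
}

#' Full evaluation report
#'
#' Confusion matrix plus per-class F1, overall (Challenge) F1, accuracy,
#' multiclass MCC, and the binary AF sensitivity/specificity/accuracy.
#'
#' @inheritParams confusion_matrix_ecg
#' @return An object of class `ecgaf_evaluation_report`.
#' @export
evaluation_report <- function(true_labels, predicted_labels) {
  cm <- confusion_matrix_ecg(true_labels, predicted_labels)
  cs <- challenge_scores(cm)
  structure(list(confusion = cm, f1 = cs$f1, overall_f1 = cs$overall_f1,
                 acc = cs$acc, mcc_multiclass = multiclass_mcc(cm),
                 binary = binary_af_scores(true_labels, predicted_labels)),
            class = "ecgaf_evaluation_report")
}

#' @export
print.ecgaf_evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  print(x$confusion)
  cat(sprintf("F1: Normal %.3f  AF %.3f  Other %.3f  Noisy %.3f\n",
              x$f1["Normal"], x$f1["AF"], x$f1["Other"], x$f1["Noisy"]))
  cat(sprintf("overall F1 %.3f  accuracy %.3f  MCC %.3f\n",
              x$overall_f1, x$acc, x$mcc_multiclass))
  b <- x$binary
  cat(sprintf("binary AF: sensitivity %s specificity %s accuracy %.3f\n",
              format(b$sensitivity, digits = 4),
              format(b$specificity, digits = 4), b$accuracy))
  invisible(x)
}

#' Write an evaluation report to JSON and the confusion matrix to CSV
#'
#' @param report An [evaluation_report()] result.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param confusion_csv Output CSV path for the confusion matrix (`NULL`
#'   to skip).
#' @return `report`, invisibly.
#' @export
write_evaluation_report <- function(report, json_path = NULL,
                                    confusion_csv = NULL) {
  if (!is.null(json_path)) {
    out <- list(f1 = as.list(report$f1), overall_f1 = report$overall_f1,
                acc = report$acc, mcc_multiclass = report$mcc_multiclass,
                binary = report$binary)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(confusion_csv))
    utils::write.csv(as.data.frame(report$confusion), confusion_csv,
                     row.names = TRUE)
  invisible(report)
}
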