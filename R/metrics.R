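# Confusion matrices and the five evaluation metrics: multiclass accuracy
# plus binary sensitivity / specificity / precision / F1 under a chosen
# positive-grade collapse.
#
# A note on the positive class: the published metric row for the
# convolutional fuser reconciles with its printed confusion matrix only
# when grade 0 ("no DR") is treated as the positive class — 3565/3673
# sensitivity, 972/1327 specificity, 3565/3920 precision.  That mapping is
# inferred from exact numeric agreement, not stated by the original
# authors, so `positive_grade` defaults to 0 to reproduce the published
# numbers but is exposed because the clinical convention (positive =
# diseased) differs.

#' Confusion matrix of grade predictions
#'
#' @param true_grades,predicted_grades Equal-length integer vectors of
#'   grades 0--4.
#' @return 5x5 integer matrix with class `confusion_matrix`; rows are the
#'   actual grade, columns the predicted grade.
#' @export
confusion_matrix <- function(true_grades, predicted_grades) {
  if (length(true_grades) != length(predicted_grades))
    stop_drh("true and predicted grades differ in length")
  if (length(true_grades) > 0) {
    true_grades <- check_grades(true_grades, "true_grades")
    predicted_grades <- check_grades(predicted_grades, "predicted_grades")
  }
  tb <- table(factor(true_grades, levels = 0:4),
              factor(predicted_grades, levels = 0:4))
  m <- matrix(as.integer(tb), 5L, 5L,
              dimnames = list(actual = 0:4, predicted = 0:4))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @noRd
as_cm <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != 5L || ncol(m) != 5L || any(m < 0))
    stop_drh("cm must be a 5x5 non-negative count matrix")
  m
}

#' Five-class accuracy
#'
#' The trace of the confusion matrix over its total — the fraction of
#' images assigned their exact grade.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
multiclass_accuracy <- function(cm) {
  m <- as_cm(cm)
  tot <- sum(m)
  if (tot == 0) stop_drh("empty confusion matrix")
  sum(diag(m)) / tot
}

#' Binary metrics under a positive-grade collapse
#'
#' Collapses the 5x5 matrix to positive (`grade == positive_grade`) versus
#' negative (all other grades) and computes sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 score
#' `2*precision*sensitivity/(precision+sensitivity)`.  A zero denominator
#' yields `NA` with the affected metric listed in `undefined` — never a
#' silent 0.
#'
#' @param cm A [confusion_matrix()].
#' @param positive_grade Grade treated as positive (default 0; see the
#'   note in the package documentation).
#' @return List with `counts` (TP, TN, FP, FN, positive_grade), the four
#'   metrics, and `undefined` (character vector of metrics with zero
#'   denominators).
#' @export
binary_metrics <- function(cm, positive_grade = 0L) {
  m <- as_cm(cm)
  if (sum(m) == 0) stop_drh("empty confusion matrix")
  positive_grade <- check_grades(positive_grade, "positive_grade")
  i <- positive_grade + 1L
  TP <- m[i, i]
  FN <- sum(m[i, ]) - TP
  FP <- sum(m[, i]) - TP
  TN <- sum(m) - TP - FN - FP
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(TP, TP + FN)
  spec <- safe_div(TN, TN + FP)
  prec <- safe_div(TP, TP + FP)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  und <- c("sensitivity", "specificity", "precision", "f1")[
    is.na(c(sens, spec, prec, f1))]
  list(counts = list(TP = TP, TN = TN, FP = FP, FN = FN,
                     positive_grade = positive_grade),
       sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
       undefined = und)
}

#' Row-normalised confusion percentages
#'
#' Each cell divided by its row sum, times 100, rounded to 2 decimals for
#' display.  Rows with zero total are returned as `NA` and listed in the
#' `flagged_rows` attribute.
#'
#' @param cm A [confusion_matrix()].
#' @return 5x5 numeric matrix of percentages.
#' @export
confusion_percentages <- function(cm) {
  m <- as_cm(cm)
  rs <- rowSums(m)
  out <- round(100 * m / ifelse(rs == 0, NA, rs), 2)
  dimnames(out) <- dimnames(m)
  attr(out, "flagged_rows") <- unname(which(rs == 0) - 1L)
  out
}

#' Evaluate grade predictions
#'
#' Bundles the full evaluation: the 5x5 confusion matrix, five-class
#' accuracy, and the binary metrics for the chosen positive grade.
#'
#' @inheritParams confusion_matrix
#' @param positive_grade Grade collapsed to positive for the binary
#'   metrics.
#' @return A list with class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `counts`, `undefined`,
#'   `positive_grade`, `confusion`.
#' @export
evaluate_model <- function(true_grades, predicted_grades,
                           positive_grade = 0L) {
  cm <- confusion_matrix(true_grades, predicted_grades)
  report_from_cm(cm, positive_grade)
}

#' Metrics report from an existing confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @param positive_grade Grade collapsed to positive.
#' @return A `metrics_report`; see [evaluate_model()].
#' @export
report_from_cm <- function(cm, positive_grade = 0L) {
  bm <- binary_metrics(cm, positive_grade)
  structure(list(accuracy = multiclass_accuracy(cm),
                 sensitivity = bm$sensitivity, specificity = bm$specificity,
                 precision = bm$precision, f1 = bm$f1,
                 counts = bm$counts, undefined = bm$undefined,
                 positive_grade = bm$counts$positive_grade,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Evaluation over", sum(unclass(x$confusion)), "images",
      sprintf("(positive grade = %d)\n", x$positive_grade))
  vals <- c(accuracy = x$accuracy, sensitivity = x$sensitivity,
            specificity = x$specificity, precision = x$precision,
            f1 = x$f1)
  print(round(vals, digits))
  cat("\nConfusion matrix (rows = actual, cols = predicted):\n")
  print(unclass(x$confusion))
  cat("\nRow percentages:\n")
  print(confusion_percentages(x$confusion))
  if (length(x$undefined))
    cat("\nUndefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metrics report as delimited text
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  df <- data.frame(metric = c("accuracy", "sensitivity", "specificity",
                              "precision", "f1"),
                   value = c(report$accuracy, report$sensitivity,
                             report$specificity, report$precision,
                             report$f1))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
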