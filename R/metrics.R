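#' Confusion matrix
#'
#' K x K count matrix with rows indexing the true class and columns the
#' predicted class.
#'
#' @param truth,predicted Vectors of class labels (coerced to a common
#'   factor level set).
#' @param classes Optional explicit class-name ordering.
#' @return Integer matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes))
    classes <- union(levels(factor(truth)), levels(factor(predicted)))
  t_ <- factor(truth, levels = classes)
  p_ <- factor(predicted, levels = classes)
  if (anyNA(t_) || anyNA(p_))
    stop("confusion_matrix: labels outside the declared class set")
  m <- table(true = t_, predicted = p_)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' One-vs-rest counts for a class
#'
#' @param cm Confusion matrix (rows = true, columns = predicted).
#' @param k Class index or name.
#' @return Named vector `c(tp, tn, fp, fn)`: `tp = cm[k, k]`,
#'   `fp` = column-k sum minus `tp`, `fn` = row-k sum minus `tp`,
#'   `tn` = total minus the other three.
#' @export
per_class_counts <- function(cm, k) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`, in the same units as its inputs
#' (percent in this package). `NA` when either input is `NA` or both are 0.
#'
#' @param precision,recall Percentages in \[0, 100\].
#' @return F1 in percent.
#' @examples
#' f1_score(96.97, 84.21)  # 90.14
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Multiclass classification report
#'
#' Overall accuracy (confusion-matrix trace over total, in percent) and
#' one-vs-rest precision, recall and F1 per class. A class with no predicted
#' (or no true) members gets `NA` for the undefined metric rather than a
#' silent zero.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Object of class `classification_report`: list with `confusion`,
#'   `accuracy` (percent), `per_class` (data frame with tp/tn/fp/fn,
#'   precision, recall, f1), and `n`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("classification_metrics: empty confusion matrix")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  per <- do.call(rbind, lapply(seq_len(nrow(cm)), function(k) {
    ct <- per_class_counts(cm, k)
    precision <- if (ct["tp"] + ct["fp"] == 0) NA_real_
      else 100 * ct["tp"] / (ct["tp"] + ct["fp"])
    recall <- if (ct["tp"] + ct["fn"] == 0) NA_real_
      else 100 * ct["tp"] / (ct["tp"] + ct["fn"])
    data.frame(class = classes[k], tp = ct[["tp"]], tn = ct[["tn"]],
               fp = ct[["fp"]], fn = ct[["fn"]],
               precision = unname(precision), recall = unname(recall),
               f1 = unname(f1_score(precision, recall)))
  }))
  structure(list(confusion = cm,
                 accuracy = 100 * sum(diag(cm)) / total,
                 per_class = per, n = total),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  cat(sprintf("<classification_report> n = %d, ACC = %.2f%%\n", x$n,
              x$accuracy))
  per <- x$per_class
  per$precision <- round(per$precision, digits)
  per$recall <- round(per$recall, digits)
  per$f1 <- round(per$f1, digits)
  print(per, row.names = FALSE)
  invisible(x)
}

#' Serialize a report to a plain list
#'
#' @param report A `classification_report`.
#' @return List ready for `jsonlite::write_json()`.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  list(accuracy = report$accuracy,
       n = report$n,
       per_class = report$per_class,
       confusion_matrix = unclass(report$confusion))
}
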