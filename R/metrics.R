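#' Confusion matrix of a prediction vector
#'
#' @param truth,pred Integer class codes (or values coercible to them).
#' @param classes Class codes fixing the row/column order (default 1..8).
#' @return A K x K integer matrix; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = 1:8) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || length(cm) == 0) {
    abort("confusion matrix must be a nonempty square matrix")
  }
  if (any(cm < 0)) abort("confusion matrix counts must be nonnegative")
  invisible(cm)
}

#' Per-class and macro F1 from a confusion matrix
#'
#' Per-class F1 is `2 * precision * recall / (precision + recall)`, defined
#' as 0 when the denominator is 0. The macro F1 is the unweighted mean of the
#' per-class F1 over the classes actually present in the truth (nonzero row
#' sums).
#'
#' @param cm A square confusion matrix (rows true, columns predicted).
#' @return `per_class_f1()`: numeric vector of per-class F1 scores (named by
#'   class if the matrix has dimnames). `macro_f1()`: a single number in
#'   \[0, 1\].
#' @export
per_class_f1 <- function(cm) {
  check_cm(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- rownames(cm)
  f1
}

#' @rdname per_class_f1
#' @export
macro_f1 <- function(cm) {
  check_cm(cm)
  present <- rowSums(cm) > 0
  if (!any(present)) abort("confusion matrix has no observed classes")
  mean(per_class_f1(cm)[present])
}
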