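#' Confusion matrix of a classification on held-out labeled pixels
#'
#' Tallies true class (rows) against predicted class (columns) over an
#' evaluation pixel set. Unclassified predictions (emitted only by the
#' parallelepiped classifier) are tallied in a dedicated column and never on
#' the diagonal, so they count as errors in every derived metric.
#'
#' @param pred a `class_map`.
#' @param eval_pixels data frame with `index` (linear pixel index) and
#'   `class` (true class name), e.g. from [sample_eval_pixels()].
#' @return object of class `sbw_confusion`: integer matrix, rows = true
#'   classes, columns = predicted classes plus `unclassified`.
#' @export
confusion_matrix <- function(pred, eval_pixels) {
  stopifnot(inherits(pred, "class_map"))
  if (!nrow(eval_pixels)) stopf("evaluation pixel set is empty")
  if (any(eval_pixels$index < 1 | eval_pixels$index > length(pred$labels)))
    stopf("evaluation pixel indices fall outside the class map")
  truth <- factor(eval_pixels$class, levels = CLASS_NAMES)
  if (anyNA(truth)) stopf("unknown true class label in evaluation set")
  plab <- pred$labels[eval_pixels$index]
  predicted <- factor(c(CLASS_NAMES, "unclassified")[ifelse(plab == 0L, 4L, plab)],
                      levels = c(CLASS_NAMES, "unclassified"))
  cm <- table(true = truth, predicted = predicted)
  structure(unclass(cm), class = "sbw_confusion")
}

#' @export
print.sbw_confusion <- function(x, ...) {
  cat("<confusion matrix> N =", sum(x), "\n")
  print(unclass(x))
  cat(sprintf("overall accuracy %.4f, kappa %.4f\n",
              overall_accuracy(x), kappa_coefficient(x)))
  invisible(x)
}

cm_check <- function(cm) {
  if (!is.matrix(cm) || any(cm < 0)) stopf("not a valid confusion matrix")
  if (sum(cm) == 0) stopf("confusion matrix has N = 0")
  k <- nrow(cm)
  if (ncol(cm) < k) stopf("confusion matrix needs at least as many columns as rows")
  k
}

#' Overall accuracy of a confusion matrix
#'
#' The share of correctly classified pixels, `sum_i A_ii / N`.
#'
#' @param cm a confusion matrix (true classes in rows; extra predicted-only
#'   columns such as `unclassified` allowed).
#' @return fraction in [0, 1].
#' @export
overall_accuracy <- function(cm) {
  k <- cm_check(cm)
  sum(diag(cm[, seq_len(k), drop = FALSE])) / sum(cm)
}

#' Kappa coefficient of a confusion matrix
#'
#' Chance-corrected agreement `(p0 - pe) / (1 - pe)` with `p0` the overall
#' accuracy and `pe = sum_i row_i * col_i / N^2` the expected chance
#' agreement from the marginals. Predicted-only columns (unclassified)
#' contribute to the predicted marginals but have no matching true row.
#'
#' @inheritParams overall_accuracy
#' @return kappa coefficient (1 = perfect agreement, 0 = chance level).
#' @export
kappa_coefficient <- function(cm) {
  k <- cm_check(cm)
  N <- sum(cm)
  p0 <- overall_accuracy(cm)
  rows <- rowSums(cm)
  cols <- colSums(cm)[seq_len(k)]
  pe <- sum(rows * cols) / N^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    stopf("kappa is undefined: chance agreement pe = 1 (degenerate single-cell matrix)")
  (p0 - pe) / (1 - pe)
}

#' Accuracy summary for one classifier on an evaluation pixel set
#'
#' @inheritParams confusion_matrix
#' @return data frame with classifier name, overall accuracy (%) and kappa.
#' @export
accuracy_summary <- function(pred, eval_pixels) {
  cm <- confusion_matrix(pred, eval_pixels)
  data.frame(classifier = pred$classifier,
             overall_accuracy_pct = 100 * overall_accuracy(cm),
             kappa = kappa_coefficient(cm))
}
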