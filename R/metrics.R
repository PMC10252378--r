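#' Confusion matrix from label vectors
#'
#' @param truth,pred Vectors of true and predicted class labels (factors or
#'   characters), equal length.
#' @param classes Optional class labels fixing the order; defaults to the
#'   union of levels seen.
#' @return An object of class `confusion_matrix`: a K x K integer matrix of
#'   counts, rows = true class, columns = predicted class.
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) {
    stopf("truth (%d) and pred (%d) differ in length", length(truth), length(pred))
  }
  classes <- classes %||%
    (if (is.factor(truth)) levels(truth) else sort(unique(c(as.character(truth),
                                                            as.character(pred)))))
  ft <- factor(as.character(truth), levels = classes)
  fp <- factor(as.character(pred), levels = classes)
  if (anyNA(ft) || anyNA(fp)) stopf("labels outside the declared class set")
  m <- table(truth = ft, pred = fp)
  structure(unclass(as.matrix(m)), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param counts Square numeric matrix of nonnegative counts, rows = true
#'   class, columns = predicted class.
#' @param classes Optional class labels.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stopf("confusion matrix must be square")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  classes <- classes %||% rownames(counts) %||% paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(truth = classes, pred = classes)
  structure(counts, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = truth, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest classification metrics for one class
#'
#' Collapses all other classes into a single negative class and reports
#' accuracy `(TP+TN)/N`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' F-score (harmonic mean of precision and recall) and specificity
#' `TN/(TN+FP)`. A ratio with a zero denominator is reported as `NA`
#' (undefined), never silently as zero.
#'
#' @param cm A [confusion_matrix()].
#' @param k Class index (or class name).
#' @return Named numeric vector `c(acc, rcl, prc, f1, spc)`.
#' @examples
#' cm <- as_confusion_matrix(rbind(c(214, 5), c(18, 291)),
#'                           c("relaxed", "stressed"))
#' class_metrics(cm, "relaxed")["rcl"] # 0.977
#' @export
class_metrics <- function(cm, k) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  if (is.character(k)) k <- match(k, rownames(m))
  stopifnot(is.finite(k), k >= 1, k <= nrow(m))
  n <- sum(m)
  tp <- m[k, k]
  fn <- sum(m[k, ]) - tp
  fp <- sum(m[, k]) - tp
  tn <- n - tp - fn - fp
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(acc = ratio(tp + tn, n),
    rcl = ratio(tp, tp + fn),
    prc = ratio(tp, tp + fp),
    f1 = {
      p <- ratio(tp, tp + fp); r <- ratio(tp, tp + fn)
      if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
    },
    spc = ratio(tn, tn + fp))
}

#' Per-class metrics table for all classes
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with one row per class and columns
#'   `class, acc, rcl, prc, f1, spc`.
#' @export
metrics_table <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rows <- t(vapply(seq_len(nrow(cm)), function(k) class_metrics(cm, k),
                   numeric(5)))
  data.frame(class = rownames(unclass(cm)), rows,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return `trace / N`, the fraction of correctly classified instances.
#' @examples
#' overall_accuracy(as_confusion_matrix(rbind(c(214, 5), c(18, 291)))) # 0.9564
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) stopf("empty confusion matrix")
  sum(diag(unclass(cm))) / n
}

#' Assemble a decision matrix from per-class metric rows
#'
#' Takes one `(model name, metrics)` row per competing model — each row the
#' five one-vs-rest metrics of a single class — and builds the
#' alternatives-by-criteria [decision_matrix()] used for ranking. All five
#' criteria are flagged beneficial and the default weights are attached.
#'
#' @param rows Named list: each element a numeric vector with entries
#'   `acc, rcl, prc, f1, spc` (as returned by [class_metrics()]).
#' @param weights Criterion weights; default [edas_default_weights()].
#' @return A [decision_matrix()] with criteria (ACC, RCL, PRC, F1, SPC).
#' @export
decision_matrix_from_metrics <- function(rows, weights = edas_default_weights()) {
  stopifnot(is.list(rows), length(rows) >= 1L)
  need <- c("acc", "rcl", "prc", "f1", "spc")
  X <- t(vapply(rows, function(r) {
    r <- unlist(r)
    if (!all(need %in% names(r))) {
      stopf("metric row missing entries: %s",
            paste(setdiff(need, names(r)), collapse = ", "))
    }
    if (anyNA(r[need])) stopf("metric row contains undefined (NA) entries")
    as.numeric(r[need])
  }, numeric(5)))
  suppressWarnings(
    decision_matrix(X, weights = weights, beneficial = rep(TRUE, 5),
                    names = names(rows) %||% paste0("model", seq_along(rows)),
                    criteria = c("ACC", "RCL", "PRC", "F1", "SPC")))
}
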