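#' Confusion table
#'
#' Cross-tabulates true against predicted class labels into a `C x C` integer
#' matrix (rows = true class, columns = predicted class).
#'
#' @param truth,predicted Vectors of class labels, same length.
#' @param classes Optional class set fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return Integer matrix with class dimnames.
#' @export
confusion_table <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) abort("truth and predicted must have equal length")
  if (!length(truth)) abort("no samples to tabulate")
  classes <- classes %||% sort(unique(c(as.character(truth), as.character(predicted))))
  t_f <- factor(as.character(truth), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  if (anyNA(t_f) || anyNA(p_f)) abort("labels outside the supplied class set")
  unclass(table(truth = t_f, predicted = p_f))
}

#' Per-class precision, recall and F1
#'
#' For each class `c`: `F1 = 2 TP / (2 TP + FP + FN)`. A degenerate class
#' (never true and never predicted, `TP + FP + FN = 0`) gets `F1 = 0` and is
#' flagged, a conservative choice that never inflates the macro mean.
#'
#' @param table A [confusion_table()].
#' @return Tibble with `class`, `support`, `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @export
per_class_f1 <- function(table) {
  if (!is.matrix(table) || nrow(table) != ncol(table)) {
    abort("table must be a square confusion matrix")
  }
  tp <- unname(diag(table))
  fn <- unname(rowSums(table)) - tp
  fp <- unname(colSums(table)) - tp
  denom_f1 <- 2 * tp + fp + fn
  degenerate <- denom_f1 == 0
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  tibble(
    class = rownames(table) %||% as.character(seq_len(nrow(table))),
    support = as.integer(rowSums(table)),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, denom_f1),
    degenerate = degenerate
  )
}

#' Macro F1
#'
#' The arithmetic mean of the per-class F1 scores, unweighted by class
#' frequency — unlike accuracy, every class counts equally, which is what
#' makes it the right summary under class imbalance.
#'
#' @param f1s Numeric vector of per-class F1 scores, or the tibble returned by
#'   [per_class_f1()].
#' @return A single value in `[0, 1]`.
#' @export
macro_f1 <- function(f1s) {
  if (is.data.frame(f1s)) f1s <- f1s$f1
  if (!length(f1s)) abort("macro F1 of an empty class set is undefined")
  mean(f1s)
}

#' Overall accuracy
#'
#' Trace of the confusion table over the total count. On imbalanced data this
#' mostly reflects majority-class performance.
#'
#' @param table A [confusion_table()].
#' @return A single value in `[0, 1]`.
#' @export
accuracy <- function(table) {
  total <- sum(table)
  if (total == 0) abort("empty confusion table")
  sum(diag(table)) / total
}

#' Evaluation report
#'
#' Bundles the per-class table with macro F1 and accuracy. `tidy()` returns
#' the per-class tibble, `glance()` the one-row summary, `autoplot()` a
#' per-class F1 bar chart, and [write_report_csv()] the CSV export.
#'
#' @param truth,predicted Class label vectors.
#' @param classes Optional fixed class set.
#' @return An `eval_report` list with elements `per_class`, `macro_f1`,
#'   `accuracy`, `table`.
#' @export
evaluation_report <- function(truth, predicted, classes = NULL) {
  tab <- confusion_table(truth, predicted, classes)
  pc <- per_class_f1(tab)
  structure(
    list(per_class = pc, macro_f1 = macro_f1(pc), accuracy = accuracy(tab), table = tab),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> macro F1 %.4f | accuracy %.4f\n", x$macro_f1, x$accuracy))
  print(x$per_class)
  invisible(x)
}

#' @rdname evaluation_report
#' @param report An `eval_report`.
#' @param path Output CSV path.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- report$per_class
  out$macro_f1 <- report$macro_f1
  out$accuracy <- report$accuracy
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble(macro_f1 = x$macro_f1, accuracy = x$accuracy,
         n_classes = nrow(x$per_class), n_samples = sum(x$table))
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot(object$per_class, aes(x = .data$class, y = .data$f1)) +
    geom_col(fill = "steelblue") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "F1 score",
         title = sprintf("Per-class F1 (macro F1 = %.3f)", object$macro_f1)) +
    theme_minimal()
}
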