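#' Score blood-type calls against reference labels
#'
#' Accuracy is computed among classified samples only: unclassified calls
#' are excluded from the denominator. When a relabel map is supplied
#' (corrected accuracy after re-typing suspected mislabels), the reference
#' labels are replaced before scoring; with an empty map the result equals
#' the uncorrected accuracy. A total-denominator accuracy is also reported
#' for transparency.
#'
#' @param calls named character vector sample -> call, or a data.frame with
#'   columns `sample_id` and `call` (as from [classify_all()]).
#' @param labels named vector sample -> reference blood type; every call
#'   must have a label.
#' @param relabel_map optional named vector sample -> corrected type.
#' @return object of class `evaluation_report`: list with `n_total`,
#'   `n_classified`, `n_unclassified`, `classification_rate`, `n_correct`,
#'   `accuracy` (NaN with a warning when nothing is classified),
#'   `accuracy_total` and `confusion` (table true x called over classified
#'   samples).
#' @export
evaluate_calls <- function(calls, labels, relabel_map = NULL) {
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$call, calls$sample_id)
  }
  missing <- setdiff(names(calls), names(labels))
  if (length(missing)) {
    stop("call(s) without a reference label: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  labels <- labels[names(calls)]
  if (!is.null(relabel_map) && length(relabel_map)) {
    hit <- names(relabel_map)[names(relabel_map) %in% names(labels)]
    labels[hit] <- relabel_map[hit]
  }

  classified <- calls != "unclassified"
  n_total <- length(calls)
  n_cls <- sum(classified)
  n_correct <- sum(calls[classified] == labels[classified])
  if (n_cls == 0L) {
    warning("no samples classified; accuracy undefined")
    accuracy <- NaN
  } else {
    accuracy <- n_correct / n_cls
  }
  lev <- c("A", "B", "AB", "O")
  confusion <- table(
    true = factor(labels[classified], levels = lev),
    called = factor(calls[classified], levels = lev)
  )
  structure(list(
    n_total = n_total, n_classified = n_cls,
    n_unclassified = n_total - n_cls,
    classification_rate = n_cls / n_total,
    n_correct = n_correct, accuracy = accuracy,
    accuracy_total = n_correct / n_total,
    confusion = confusion
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("classified %d/%d (%.1f%%); accuracy among classified %d/%d (%.1f%%)\n",
              x$n_classified, x$n_total, 100 * x$classification_rate,
              x$n_correct, x$n_classified, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Convert an evaluation report to a one-row data.frame
#'
#' Machine-readable counterpart of the printed report, full precision.
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return one-row data.frame.
#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(n_total = x$n_total, n_classified = x$n_classified,
             n_unclassified = x$n_unclassified,
             classification_rate = x$classification_rate,
             n_correct = x$n_correct, accuracy = x$accuracy,
             accuracy_total = x$accuracy_total)
}
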