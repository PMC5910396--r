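#' One-vs-rest confusion counts
#'
#' For every class in `levels`, counts true/false positives and negatives
#' treating that class as positive and all others as negative. Inputs are the
#' argmax-predicted labels and the true labels.
#'
#' @param predicted,truth Vectors (or factors) of equal length with labels
#'   drawn from `levels`.
#' @param levels Character vector of all class labels; defaults to the sorted
#'   union of the observed labels.
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`; each row
#'   satisfies tp + fp + fn + tn = number of records.
#' @export
confusion_counts <- function(predicted, truth, levels = NULL) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length.")
  }
  if (is.null(levels)) {
    levels <- sort(unique(c(as.character(predicted), as.character(truth))))
  }
  predicted <- factor(as.character(predicted), levels = levels)
  truth <- factor(as.character(truth), levels = levels)
  if (anyNA(predicted) || anyNA(truth)) {
    abort("Labels outside `levels` encountered.")
  }
  n <- length(truth)
  purrr::map_dfr(levels, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   tn = n - tp - fp - fn)
  })
}

degenerate_zero <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    warn(paste0(what, ": 0/0 denominator; reporting 0 for the degenerate case(s)."))
  }
  out
}

#' Classification metrics from one-vs-rest counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean of the
#' two, accuracy = (TP+TN)/(TP+FP+FN+TN). Degenerate 0/0 denominators return
#' 0 with a warning. All are vectorized over classes.
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @param precision,recall Metric values for [f1_score()].
#' @return Numeric value(s) in [0, 1].
#' @name classification-metrics
NULL

#' @rdname classification-metrics
#' @export
precision_score <- function(tp, fp) degenerate_zero(tp, tp + fp, "precision")

#' @rdname classification-metrics
#' @export
recall_score <- function(tp, fn) degenerate_zero(tp, tp + fn, "recall")

#' @rdname classification-metrics
#' @export
f1_score <- function(precision, recall) {
  degenerate_zero(2 * precision * recall, precision + recall, "F1")
}

#' @rdname classification-metrics
#' @export
accuracy_score <- function(tp, fp, fn, tn) {
  degenerate_zero(tp + tn, tp + fp + fn + tn, "accuracy")
}

#' Evaluate a fitted model on a labeled dataset
#'
#' Runs the forward pass on every record, takes the argmax diagnosis, builds
#' one-vs-rest confusion counts, and reports per-class precision, recall, F1
#' and accuracy together with macro averages (unweighted means over classes;
#' micro and label-frequency-weighted averages are also available) and the
#' overall multiclass accuracy (fraction of records whose top diagnosis is
#' correct).
#'
#' @param object A fitted [fit_emrcnn()] model.
#' @param data Labeled records with the model's text and label columns.
#' @param average Aggregation scheme for the summary row: `"macro"`
#'   (default), `"micro"`, or `"weighted"`.
#' @return An `emrcnn_metrics` object: list with `per_class` (tibble),
#'   `summary` (one-row tibble with aggregated precision/recall/F1 and
#'   overall accuracy), `confusion` (counts tibble), `average`, `n`.
#' @export
evaluate_model <- function(object, data, average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  stopifnot(inherits(object, "emrcnn"))
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) abort("Cannot evaluate on an empty dataset.")
  truth <- as.character(data[[object$label_col]])
  pred <- as.character(predict(object, data, type = "class")$.pred_class)
  metrics_from_labels(pred, truth, levels = object$label_levels,
                      average = average)
}

# Shared by evaluate_model() and tests: metrics from label vectors alone.
metrics_from_labels <- function(predicted, truth, levels = NULL,
                                average = "macro") {
  counts <- confusion_counts(predicted, truth, levels)
  per_class <- counts |>
    dplyr::mutate(
      precision = precision_score(.data$tp, .data$fp),
      recall = recall_score(.data$tp, .data$fn),
      f1 = f1_score(.data$precision, .data$recall),
      accuracy = accuracy_score(.data$tp, .data$fp, .data$fn, .data$tn),
      support = .data$tp + .data$fn
    )
  overall_acc <- mean(as.character(predicted) == as.character(truth))
  agg <- switch(average,
    macro = dplyr::summarise(per_class,
      precision = mean(.data$precision),
      recall = mean(.data$recall),
      f1 = mean(.data$f1)),
    weighted = dplyr::summarise(per_class,
      precision = sum(.data$precision * .data$support) / sum(.data$support),
      recall = sum(.data$recall * .data$support) / sum(.data$support),
      f1 = sum(.data$f1 * .data$support) / sum(.data$support)),
    micro = {
      tp <- sum(per_class$tp); fp <- sum(per_class$fp); fn <- sum(per_class$fn)
      p <- precision_score(tp, fp); r <- recall_score(tp, fn)
      tibble::tibble(precision = p, recall = r, f1 = f1_score(p, r))
    })
  summary <- dplyr::mutate(agg, accuracy = overall_acc, average = average)
  structure(
    list(per_class = per_class, summary = summary,
         confusion = counts, average = average, n = length(truth)),
    class = "emrcnn_metrics"
  )
}

#' @export
print.emrcnn_metrics <- function(x, ...) {
  cat("<emrcnn_metrics> ", x$n, " records, ", nrow(x$per_class),
      " classes (", x$average, " average)\n", sep = "")
  print(x$per_class[, c("class", "precision", "recall", "f1", "support")])
  cat(sprintf("overall accuracy %.4f | %s P %.4f R %.4f F1 %.4f\n",
              x$summary$accuracy, x$average, x$summary$precision,
              x$summary$recall, x$summary$f1))
  invisible(x)
}

#' @export
#' @method tidy emrcnn_metrics
tidy.emrcnn_metrics <- function(x, ...) {
  dplyr::bind_rows(
    x$per_class[, c("class", "precision", "recall", "f1", "accuracy", "support")],
    tibble::tibble(class = paste0("(", x$average, ")"),
                   precision = x$summary$precision,
                   recall = x$summary$recall,
                   f1 = x$summary$f1,
                   accuracy = x$summary$accuracy,
                   support = sum(x$per_class$support))
  )
}

#' @export
#' @method glance emrcnn_metrics
glance.emrcnn_metrics <- function(x, ...) {
  x$summary
}

#' Write a metrics report to CSV or JSON
#'
#' @param metrics An [evaluate_model()] result.
#' @param path Output file; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "emrcnn_metrics"))
  tab <- tidy(metrics)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE)
  } else {
    readr::write_csv(tab, path)
  }
  invisible(path)
}
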