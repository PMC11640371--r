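# Multiclass evaluation: confusion matrix and the metric set used for
# model comparison (per-class one-vs-rest sensitivity, specificity,
# precision, F1; macro and micro averages; overall accuracy).

#' Confusion matrix
#'
#' @param truth,predicted Equal-length label vectors (factors, characters,
#'   or integer codes).
#' @param labels Optional class-level ordering; defaults to the union of
#'   observed levels (in [class_labels()] order where applicable).
#' @return A K x K integer matrix; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(labels)) {
    seen <- unique(c(truth, predicted))
    canon <- class_labels()
    labels <- c(intersect(canon, seen), sort(setdiff(seen, canon)))
  }
  if (!all(truth %in% labels) || !all(predicted %in% labels)) {
    stop("labels outside the declared class set", call. = FALSE)
  }
  tab <- table(factor(truth, levels = labels),
               factor(predicted, levels = labels))
  m <- matrix(as.integer(tab), length(labels), length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

safe_rate <- function(num, den) {
  ifelse(den > 0, num / den, 0)
}

#' Evaluation report from a confusion matrix
#'
#' Per class c (one-vs-rest): sensitivity (= recall) TP/(TP+FN),
#' specificity TN/(TN+FP), precision TP/(TP+FP), F1 = 2*prec*sens/
#' (prec+sens). Macro averages are unweighted class means; micro averages
#' pool counts over classes. Rates with zero denominators are reported as 0
#' and the affected classes are flagged in `zero_denominator`.
#'
#' @param cm A K x K confusion matrix (rows = true classes).
#' @param average `"macro"` (default) or `"micro"` for the summary block.
#' @return A list of class `eval_report`: `confusion`, `per_class` (data
#'   frame), `accuracy`, `macro` and `micro` summaries, `n`, and
#'   `zero_denominator` flags.
#' @export
metrics_from_cm <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) {
    stop("`cm` must be a square nonnegative count matrix", call. = FALSE)
  }
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- total - tp - fn - fp
  sens <- safe_rate(tp, tp + fn)
  spec <- safe_rate(tn, tn + fp)
  prec <- safe_rate(tp, tp + fp)
  f1 <- safe_rate(2 * prec * sens, prec + sens)
  flagged <- labels[(tp + fn) == 0 | (tn + fp) == 0 | (tp + fp) == 0 |
                      (prec + sens) == 0]
  per_class <- data.frame(class = labels, tp = tp, fp = fp, fn = fn, tn = tn,
                          sensitivity = sens, specificity = spec,
                          precision = prec, recall = sens, f1 = f1,
                          row.names = NULL, stringsAsFactors = FALSE)
  macro <- list(sensitivity = mean(sens), specificity = mean(spec),
                precision = mean(prec), recall = mean(sens), f1 = mean(f1))
  micro_prec <- safe_rate(sum(tp), sum(tp + fp))
  micro_sens <- safe_rate(sum(tp), sum(tp + fn))
  micro <- list(sensitivity = micro_sens,
                specificity = safe_rate(sum(tn), sum(tn + fp)),
                precision = micro_prec, recall = micro_sens,
                f1 = safe_rate(2 * micro_prec * micro_sens,
                               micro_prec + micro_sens))
  structure(list(confusion = cm, per_class = per_class,
                 accuracy = sum(tp) / total,
                 macro = macro, micro = micro, n = total,
                 average = average,
                 zero_denominator = flagged),
            class = "eval_report")
}

#' Evaluate predictions directly
#'
#' Convenience wrapper: builds the confusion matrix and computes the report.
#'
#' @inheritParams confusion_matrix
#' @inheritParams metrics_from_cm
#' @return An `eval_report`.
#' @export
evaluate_predictions <- function(truth, predicted, labels = NULL,
                                 average = "macro") {
  metrics_from_cm(confusion_matrix(truth, predicted, labels), average)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d samples — accuracy %.4f\n", x$n,
              x$accuracy))
  cat(sprintf("macro: SE %.4f  SP %.4f  F1 %.4f\n",
              x$macro$sensitivity, x$macro$specificity, x$macro$f1))
  print(x$confusion)
  if (length(x$zero_denominator) > 0) {
    cat("NOTE: zero-denominator rates reported as 0 for: ",
        paste(x$zero_denominator, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' Serialization round-trips losslessly (full double precision).
#'
#' @param report An `eval_report`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_eval_report()` returns the restored
#'   report.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::serializeJSON(unclass(report), digits = 17), path)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  structure(obj, class = "eval_report")
}

#' Model-comparison table
#'
#' One row per evaluated model in the standard comparison layout
#' (sensitivity, specificity, accuracy, F1 — macro-averaged).
#'
#' @param reports Named list of `eval_report` objects.
#' @return A data frame with columns `model`, `sensitivity`, `specificity`,
#'   `accuracy`, `f1`.
#' @export
comparison_table <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, sensitivity = r$macro$sensitivity,
               specificity = r$macro$specificity, accuracy = r$accuracy,
               f1 = r$macro$f1, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Render a confusion matrix to a PNG file
#'
#' @param cm Confusion matrix (counts).
#' @param path Output PNG path.
#' @return `path` invisibly.
#' @export
plot_confusion <- function(cm, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off(), add = TRUE)
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true")
  graphics::axis(1, at = seq_len(k), labels = colnames(cm), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm)), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, k - i + 1, cm[i, j], cex = 0.9)
  }
  invisible(path)
}
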