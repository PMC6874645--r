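#' Confusion counts for binary predictions
#'
#' Tallies the 2x2 confusion matrix: TP (true cancer predicted cancer),
#' FP (non-cancer predicted cancer), FN (cancer missed — the clinically
#' critical cell) and TN.
#'
#' @param y_true,y_pred equal-length vectors with entries in `{0, 1}`.
#' @return object of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
#' @examples
#' confusion(c(1, 0), c(1, 0)) # TP = 1, TN = 1
confusion <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stopf("length mismatch: %d vs %d", length(y_true), length(y_pred))
  if (!is_binary01(y_true) || !is_binary01(y_pred)) stopf("labels must be 0/1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0),
                 TN = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_counts")
}

#' Evaluation measures from confusion counts
#'
#' Computes the five measures used throughout the pipeline:
#' * accuracy = (TP + TN) / (TP + TN + FP + FN)
#' * precision = TP / (TP + FP)
#' * recall = TP / (TP + FN)
#' * F1 = 2 * precision * recall / (precision + recall)
#'       = 2 TP / (2 TP + FP + FN)
#' * FNR = FN / (TP + FN), the missed-diagnosis rate — the complement of
#'   recall and the clinically emphasized measure under class imbalance.
#'
#' A degenerate denominator (e.g. precision when nothing was predicted
#' positive) yields value 0 together with an `undefined` flag rather than
#' an error, so that averaging over repeated splits never aborts.
#'
#' @param c a [confusion()] object, or a list with fields TP, FP, FN, TN.
#' @return object of class `metrics_report`: numeric fields `accuracy`,
#'   `precision`, `recall`, `f1`, `fnr`, logical vector `undefined`
#'   (per-measure flags) and the echoed `counts`.
#' @export
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
compute_metrics <- function(c) {
  if (!inherits(c, "confusion_counts")) {
    stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(c)))
    c <- structure(c[c("TP", "FP", "FN", "TN")], class = "confusion_counts")
  }
  if (any(unlist(c[c("TP", "FP", "FN", "TN")]) < 0)) stopf("negative confusion count")
  total <- c$TP + c$FP + c$FN + c$TN
  if (total == 0) stopf("all confusion counts are zero")
  safe <- function(num, den) if (den > 0) num / den else 0
  und <- c(accuracy = FALSE,
           precision = (c$TP + c$FP) == 0,
           recall = (c$TP + c$FN) == 0,
           f1 = (2 * c$TP + c$FP + c$FN) == 0,
           fnr = (c$TP + c$FN) == 0)
  structure(list(accuracy = (c$TP + c$TN) / total,
                 precision = safe(c$TP, c$TP + c$FP),
                 recall = safe(c$TP, c$TP + c$FN),
                 f1 = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN),
                 fnr = safe(c$FN, c$TP + c$FN),
                 undefined = und,
                 counts = c),
            class = "metrics_report")
}

metric_names <- c("accuracy", "precision", "recall", "f1", "fnr")

#' Format a metrics report for display
#'
#' `mode = "round4"` rounds to four decimals (the convention of the
#' summary tables); `mode = "truncate2"` truncates — not rounds — to two
#' decimals, the style of the worked narrative example (8/9 displays as
#' 0.88).
#'
#' @param report a `metrics_report`.
#' @param mode `"round4"` or `"truncate2"`.
#' @return named numeric vector of the five measures.
#' @export
format_metrics <- function(report, mode = c("round4", "truncate2")) {
  mode <- match.arg(mode)
  vals <- unlist(report[metric_names])
  if (mode == "round4") round(vals, 4) else trunc(vals * 100) / 100
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- format_metrics(x)
  cat("<metrics_report>",
      paste(sprintf("%s=%.4f%s", names(vals), vals,
                    ifelse(x$undefined, "*", "")), collapse = "  "),
      "\n")
  if (any(x$undefined)) cat("  (* degenerate denominator, value set to 0)\n")
  invisible(x)
}

#' One-row data frame of a metrics report
#'
#' Convenience for CSV export and aggregation.
#'
#' @param report a `metrics_report`.
#' @return `data.frame` with the five measures and the four counts.
#' @export
metrics_row <- function(report) {
  data.frame(accuracy = report$accuracy, precision = report$precision,
             recall = report$recall, f1 = report$f1, fnr = report$fnr,
             TP = report$counts$TP, FP = report$counts$FP,
             FN = report$counts$FN, TN = report$counts$TN)
}
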