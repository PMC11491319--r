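#' Confusion counts for benign/malignant labels
#'
#' Malignant is the positive class, following the clinical convention that
#' sensitivity measures disease detection.
#'
#' @param truth,predicted Character vectors of `"benign"` / `"malignant"`,
#'   equal length.
#' @return Object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' confusion(c("malignant", "malignant", "benign", "benign"),
#'           c("malignant", "benign", "benign", "malignant"))
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  ok <- c("benign", "malignant")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    abort("labels must be 'benign' or 'malignant'.")
  }
  pos_t <- truth == "malignant"
  pos_p <- predicted == "malignant"
  structure(
    list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
         FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>  TP:", x$TP, " TN:", x$TN,
      " FP:", x$FP, " FN:", x$FN, "\n")
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' accuracy `(TP+TN)/N`, sensitivity (= recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`. A metric whose denominator is zero
#' is reported as `NA` (undefined), never coerced to 0.
#'
#' @param counts A `confusion_counts` object.
#' @param auc Optional AUC to carry along (e.g. from [roc_curve()]).
#' @return Object of class `metrics_report` (named list of fractions).
#' @export
#' @examples
#' metrics(confusion_counts(TP = 50, TN = 40, FP = 5, FN = 5))
metrics <- function(counts, auc = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  N <- counts$TP + counts$TN + counts$FP + counts$FN
  if (N == 0) abort("confusion counts are all zero.")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      accuracy = (counts$TP + counts$TN) / N,
      sensitivity = safe_div(counts$TP, counts$TP + counts$FN),
      specificity = safe_div(counts$TN, counts$TN + counts$FP),
      precision = safe_div(counts$TP, counts$TP + counts$FP),
      auc = if (is.null(auc)) NA_real_ else auc,
      counts = counts
    ),
    class = "metrics_report"
  )
}

#' Construct confusion counts directly
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP, TN, FP, FN)
  if (any(v < 0) || any(v != floor(v))) abort("counts must be non-negative integers.")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat("<metrics_report>\n")
  cat("  accuracy:   ", fmt(x$accuracy), "\n")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  precision:  ", fmt(x$precision), "\n")
  if (!is.na(x$auc)) cat("  AUC:        ", sprintf("%.4f", x$auc), "\n")
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `value` (fraction), `percent`
#'   (value on the 0-100 scale, rounded to 2 decimals).
#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) {
  nm <- c("accuracy", "sensitivity", "specificity", "precision", "auc")
  vals <- unname(vapply(nm, function(m) x[[m]], numeric(1)))
  tibble(metric = nm, value = vals, percent = round(100 * vals, 2))
}

#' @rdname tidy.metrics_report
#' @exportS3Method generics::glance
glance.metrics_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, precision = x$precision, auc = x$auc,
         n = x$counts$TP + x$counts$TN + x$counts$FP + x$counts$FN)
}

#' ROC curve and AUC
#'
#' Computes the true/false positive rate at every distinct score threshold
#' (predicting malignant when `score >= threshold`), with the `(0,0)` and
#' `(1,1)` endpoints, and the area under the curve by the trapezoidal rule.
#' The trapezoid AUC equals the Mann-Whitney probability
#' `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param scores Malignant-class scores (e.g. predicted probabilities).
#' @param truth Character labels, `"benign"` / `"malignant"`; both classes
#'   must be present.
#' @return Object of class `roc_result`: `points` tibble
#'   `(threshold, fpr, tpr)` and `auc`.
#' @export
#' @examples
#' roc_curve(c(0.9, 0.8, 0.4, 0.3),
#'           c("malignant", "benign", "malignant", "benign"))$auc  # 0.75
roc_curve <- function(scores, truth) {
  if (length(scores) != length(truth)) abort("`scores`/`truth` length mismatch.")
  pos <- truth == "malignant"
  if (!any(pos) || all(pos)) abort("need at least one positive and one negative.")
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(pos); Ng <- sum(!pos)
  tpr <- vapply(th, function(t) sum(scores >= t & pos) / P, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !pos) / Ng, numeric(1))
  points <- tibble(
    threshold = c(Inf, th, -Inf),
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1)
  )
  points <- dplyr::distinct(points, .data$fpr, .data$tpr, .keep_all = TRUE)
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result>  AUC:", sprintf("%.4f", x$auc),
      " (", nrow(x$points), "points )\n")
  invisible(x)
}

#' @rdname roc_curve
#' @param x,object A `roc_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$points

#' @rdname roc_curve
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Prediction error histogram
#'
#' Bins the signed errors `target - predicted_probability` (target 1 for
#' malignant, 0 for benign) into `n_bins` equal-width bins on `[-1, 1]`,
#' per data split. A well-calibrated model concentrates mass near zero.
#'
#' @param prob_malignant Predicted malignant probabilities.
#' @param truth Character labels.
#' @param split Optional character vector of split names (train/val/test);
#'   default a single `"all"` split.
#' @param n_bins Number of bins (>= 1).
#' @return Tibble with `split`, `bin_left`, `bin_right`, `bin_mid`, `count`.
#' @export
error_histogram <- function(prob_malignant, truth, split = NULL, n_bins = 20L) {
  if (n_bins < 1L) abort("`n_bins` must be at least 1.")
  if (length(prob_malignant) != length(truth)) abort("length mismatch.")
  if (is.null(split)) split <- rep("all", length(truth))
  target <- as.numeric(truth == "malignant")
  err <- target - prob_malignant
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(err, breaks, rightmost.closed = TRUE), 1L), n_bins)
  df <- tibble(split = split, bin = bin)
  counts <- df |>
    dplyr::count(.data$split, .data$bin, name = "count") |>
    tidyr::complete(split = unique(split), bin = seq_len(n_bins),
                    fill = list(count = 0L))
  counts |>
    dplyr::mutate(
      bin_left = breaks[.data$bin],
      bin_right = breaks[.data$bin + 1L],
      bin_mid = (.data$bin_left + .data$bin_right) / 2
    ) |>
    dplyr::select("split", "bin_left", "bin_right", "bin_mid", "count")
}
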