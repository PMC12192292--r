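# Binary classification evaluation (confusion counts, scalar metrics,
# ROC/AUC) and exploratory statistics (Pearson matrix, histogram counts).

#' Confusion counts for binary labels
#'
#' Positive class is label 1.
#'
#' @param y_true,y_pred Equal-length vectors of 0/1 labels.
#' @return An object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("dimension error: y_true and y_pred lengths differ", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 tn = sum(y_true == 0L & y_pred == 0L),
                 fn = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_matrix")
}

# 0-denominator convention shared by the scalar metrics: return 0, warn.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); returning 0", what))
    return(0)
  }
  num / den
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2PR/(P+R)` and false-positive rate `FP/(TN+FP)`. Metrics whose
#' denominator is zero are reported as 0 with a warning, so degenerate folds
#' still yield a complete report.
#'
#' @param cm A [confusion()] result with at least one counted sample.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `fpr`.
#' @export
scalar_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) stop("confusion matrix counts no samples", call. = FALSE)
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (cm$tp + cm$tn) / total,
       precision = precision,
       recall = recall,
       f1 = f1,
       fpr = safe_ratio(cm$fp, cm$tn + cm$fp, "false positive rate"))
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over every distinct score (descending, tied scores
#' grouped), anchors the curve at (0,0) and (1,1), and integrates the area
#' by the trapezoid rule. This AUC equals the Mann-Whitney statistic
#' (probability a random positive outscores a random negative, ties counted
#' one half) up to floating-point error.
#'
#' @param y_true Vector of 0/1 labels containing both classes.
#' @param scores Numeric scores, larger = more positive.
#' @return List with `roc_points` (two-column matrix of FPR, TPR, FPR
#'   non-decreasing) and `auc` (scalar in `[0, 1]`).
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) {
    stop("dimension error: labels and scores lengths differ", call. = FALSE)
  }
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("metric error: both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(scores >= s & y_true == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(s) sum(scores >= s & y_true == 0L) / n_neg,
                numeric(1))
  pts <- rbind(c(0, 0), cbind(fpr, tpr), c(1, 1))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  dimnames(pts) <- list(NULL, c("fpr", "tpr"))
  auc <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                                     utils::tail(pts[, "tpr"], -1)) / 2)
  list(roc_points = pts, auc = auc)
}

#' Full evaluation report
#'
#' Convenience wrapper combining [confusion()], [scalar_metrics()] and
#' [roc_auc()].
#'
#' @param y_true 0/1 labels.
#' @param y_pred 0/1 predictions.
#' @param scores Optional ranking scores for the ROC/AUC part; when missing
#'   the report carries `auc = NA` and no ROC points.
#' @return An object of class `metrics_report`: scalar metrics plus `auc`
#'   and `roc_points`.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL) {
  rep <- scalar_metrics(confusion(y_true, y_pred))
  if (!is.null(scores)) {
    roc <- roc_auc(y_true, scores)
    rep$auc <- roc$auc
    rep$roc_points <- roc$roc_points
  } else {
    rep$auc <- NA_real_
    rep$roc_points <- NULL
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy=%.3f precision=%.3f recall=%.3f f1=%.3f fpr=%.3f auc=%s\n",
    x$accuracy, x$precision, x$recall, x$f1, x$fpr,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Pearson correlation matrix of features and label
#'
#' Correlations among the 8 features plus the outcome (9 x 9, symmetric,
#' unit diagonal). Pairs involving a constant column are undefined and
#' reported as `NA` with a warning rather than an error.
#'
#' @param table A [feature_table()] with >= 2 rows.
#' @return 9 x 9 numeric matrix with dimension names.
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$features) < 2L) stop("need >= 2 rows", call. = FALSE)
  m <- cbind(table$features, Outcome = as.numeric(table$labels))
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  if (any(const)) {
    warning(sprintf("constant column(s) give undefined correlations: %s",
                    paste(colnames(m)[const], collapse = ", ")))
  }
  r
}

#' Equal-width histogram counts
#'
#' Bins span `[min, max]` with left-closed bins and a closed right-most bin,
#' so counts always sum to `length(values)`. A degenerate all-equal input
#' collapses to a single bin.
#'
#' @param values Non-empty numeric vector.
#' @param n_bins Number of bins (>= 1).
#' @return List with `bin_edges` (length `n_bins + 1`) and integer `counts`
#'   (length `n_bins`).
#' @export
histogram_counts <- function(values, n_bins) {
  if (length(values) == 0L) stop("values must be non-empty", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    return(list(bin_edges = c(lo, hi), counts = length(values)))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  list(bin_edges = edges,
       counts = as.integer(tabulate(idx, nbins = n_bins)))
}
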