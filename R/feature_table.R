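# The tabular currency shared by every module: 8 named clinical features
# plus a binary outcome label.

#' Canonical feature column names
#'
#' The fixed, ordered set of eight predictor names used throughout the
#' package (Pima-style clinical features).
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' pima_feature_names()
pima_feature_names <- function() {
  c("Pregnancies", "Glucose", "Blood Pressure", "Skin Thickness",
    "Insulin", "BMI", "Diabetes Pedigree Function", "Age")
}

#' Construct a feature table
#'
#' A `feature_table` bundles an n x 8 numeric feature matrix (columns in the
#' canonical [pima_feature_names()] order) with a binary outcome vector.
#' Label 1 is the positive (disease-present) class.
#'
#' @param features Numeric matrix or data frame with 8 columns.
#' @param labels Vector of 0/1 labels, one per row.
#' @return An object of class `feature_table` with elements `features`
#'   (matrix with canonical column names) and `labels` (integer vector).
#' @export
feature_table <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (ncol(features) != 8L) {
    stop(sprintf("expected exactly 8 feature columns, got %d", ncol(features)),
         call. = FALSE)
  }
  colnames(features) <- pima_feature_names()
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` length must equal the number of feature rows", call. = FALSE)
  }
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    bad <- which(!(labels %in% c(0L, 1L)))[1L]
    stop(sprintf("labels must be 0 or 1; offending row %d", bad), call. = FALSE)
  }
  if (length(features) && !all(is.finite(features))) {
    stop("all feature values must be finite", call. = FALSE)
  }
  structure(list(features = features, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  n <- nrow(x$features)
  pos <- if (n) mean(x$labels) else NA_real_
  cat(sprintf("<feature_table> %d rows, 8 features, positive fraction %.3f\n",
              n, pos))
  invisible(x)
}

#' Number of rows in a feature table
#' @param table A [feature_table()].
#' @return Integer row count.
#' @export
n_rows <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  nrow(table$features)
}

# Normalize a header name for tolerant matching: case-insensitive and
# ignoring spaces, dots and underscores ("Blood.Pressure" == "blood pressure").
normalize_name <- function(x) gsub("[ ._]", "", tolower(trimws(x)))

#' Read a feature table from CSV
#'
#' Expects a header row containing the eight canonical feature columns (name
#' matching is case-insensitive and whitespace/punctuation tolerant) plus a
#' binary label column. Extra columns are rejected only if a required one is
#' missing; row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param label_column Name of the outcome column (default "Outcome").
#' @return A [feature_table()].
#' @export
read_feature_csv <- function(path, label_column = "Outcome") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- c(pima_feature_names(), label_column)
  idx <- match(normalize_name(want), normalize_name(names(df)))
  if (anyNA(idx)) {
    missing <- want[is.na(idx)]
    stop(sprintf("schema error: expected columns [%s]; missing [%s]; found [%s]",
                 paste(want, collapse = ", "),
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  labels_raw <- df[[idx[9L]]]
  ok <- !is.na(labels_raw) & labels_raw %in% c(0, 1)
  if (!all(ok)) {
    stop(sprintf("label column '%s' must contain only 0/1; offending row %d",
                 label_column, which(!ok)[1L]), call. = FALSE)
  }
  feature_table(as.matrix(df[idx[1:8]]), labels_raw)
}

#' Write a feature table to CSV
#'
#' Writes a header row plus one line per observation, with the label as the
#' last column.
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @param label_column Header name for the outcome column (default "Outcome").
#' @return The path, invisibly.
#' @export
write_feature_csv <- function(table, path, label_column = "Outcome") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$features, check.names = FALSE)
  df[[label_column]] <- table$labels
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE),
    error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  invisible(path)
}
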