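# Preprocessing pipeline: zero-as-missing mean imputation, min-max
# normalization, stratified splitting, SMOTE oversampling.

#' Replace zero-coded missing values by the nonzero column mean
#'
#' In Pima-style data, zeros in Blood Pressure, Skin Thickness and Insulin
#' encode missing measurements. Each zero in the named columns is replaced by
#' the mean of that column's *nonzero* entries, computed on the input table;
#' all other cells are untouched.
#'
#' @param table A [feature_table()].
#' @param columns Character vector of feature column names to impute
#'   (default the three missingness-prone columns). May be empty.
#' @return A new [feature_table()].
#' @export
impute_zero_as_missing_mean <- function(table,
                                        columns = c("Blood Pressure",
                                                    "Skin Thickness",
                                                    "Insulin")) {
  stopifnot(inherits(table, "feature_table"))
  if (length(columns) == 0L) return(table)
  feats <- table$features
  miss <- setdiff(columns, colnames(feats))
  if (length(miss)) {
    stop(sprintf("unknown column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (cn in columns) {
    x <- feats[, cn]
    nz <- x != 0
    if (!any(nz)) {
      stop(sprintf("imputation error: column '%s' is entirely zero", cn),
           call. = FALSE)
    }
    x[!nz] <- mean(x[nz])
    feats[, cn] <- x
  }
  feature_table(feats, table$labels)
}

#' Fit a min-max normalization model
#'
#' Records the per-column minimum and maximum of the feature matrix, the
#' statistics needed to rescale each feature to `[0, 1]` via
#' `(X - Xmin) / (Xmax - Xmin)`.
#'
#' @param table A [feature_table()] with at least one row.
#' @return An object of class `minmax_model` with numeric vectors `x_min`
#'   and `x_max`.
#' @export
fit_minmax <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$features) < 1L) {
    stop("cannot fit normalization on an empty table", call. = FALSE)
  }
  structure(list(x_min = apply(table$features, 2, min),
                 x_max = apply(table$features, 2, max)),
            class = "minmax_model")
}

#' Apply a min-max normalization model
#'
#' Rescales every cell to `(X - Xmin) / (Xmax - Xmin)` using the fitted
#' extrema. Columns that were constant at fit time (`Xmax == Xmin`) map to 0
#' with a warning. Applying a training-set model to test data may produce
#' values outside `[0, 1]`; that is intentional (no re-fitting on test data).
#'
#' @param table A [feature_table()].
#' @param model A `minmax_model` from [fit_minmax()].
#' @return A normalized [feature_table()].
#' @export
apply_minmax <- function(table, model) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "minmax_model"))
  if (!identical(names(model$x_min), colnames(table$features))) {
    stop("schema error: normalization model columns do not match the table",
         call. = FALSE)
  }
  feats <- table$features
  rng <- model$x_max - model$x_min
  degenerate <- rng <= 0
  if (any(degenerate)) {
    warning(sprintf("constant column(s) mapped to 0: %s",
                    paste(names(model$x_min)[degenerate], collapse = ", ")))
  }
  for (j in seq_len(ncol(feats))) {
    if (degenerate[j]) {
      feats[, j] <- 0
    } else {
      feats[, j] <- (feats[, j] - model$x_min[j]) / rng[j]
    }
  }
  feature_table(feats, table$labels)
}

# Largest-remainder apportionment of round(total * fraction) across classes:
# start from floor(count_k * fraction) and hand out the remaining units in
# decreasing order of fractional remainder.
largest_remainder_counts <- function(class_counts, fraction) {
  target_total <- round(sum(class_counts) * fraction)
  base <- floor(class_counts * fraction)
  remainder <- class_counts * fraction - base
  short <- target_total - sum(base)
  if (short > 0) {
    give <- order(remainder, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  } else if (short < 0) {
    take <- order(remainder, decreasing = FALSE)[seq_len(-short)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

#' Stratified train/test split
#'
#' Splits the table so that each class contributes
#' `round(class_count * train_fraction)` rows to the training part
#' (largest-remainder rounding keeps the overall training size equal to
#' `round(n * train_fraction)`). Assignment within a class is a seeded
#' permutation, so a fixed seed reproduces the split exactly.
#'
#' @param table A [feature_table()]; each class must hold at least 2 rows.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `split_result` with elements `train`, `test`
#'   (both [feature_table()]s) and `train_fraction`.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  stop_if_not_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  counts <- c(`0` = sum(table$labels == 0L), `1` = sum(table$labels == 1L))
  if (any(counts < 2L)) {
    stop(sprintf("stratification error: class %s has %d row(s); need >= 2",
                 names(counts)[counts < 2L][1L], min(counts)), call. = FALSE)
  }
  n_train <- largest_remainder_counts(counts, train_fraction)
  train_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      rows <- which(table$labels == cl)
      perm <- rows[sample.int(length(rows))]
      perm[seq_len(n_train[cl + 1L])]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_rows(table)), train_idx)
  structure(list(
    train = feature_table(table$features[train_idx, , drop = FALSE],
                          table$labels[train_idx]),
    test = feature_table(table$features[test_idx, , drop = FALSE],
                         table$labels[test_idx]),
    train_fraction = train_fraction
  ), class = "split_result")
}

#' SMOTE oversampling to exact class balance
#'
#' Appends synthetic minority-class rows until both classes have equal
#' counts. Each synthetic row is `s + lambda * (n - s)` where `s` is a
#' minority seed row (chosen by a seeded round-robin over a permutation of
#' the minority class), `n` one of its `k_neighbors` nearest minority
#' neighbors by Euclidean distance on the feature columns (picked uniformly),
#' and `lambda` uniform on `[0, 1]`. Original rows are returned unchanged and
#' first.
#'
#' @param table A [feature_table()]; the minority class needs >= 2 rows.
#' @param k_neighbors Number of nearest neighbors to interpolate toward
#'   (default 5); silently capped at minority size - 1 with a warning.
#' @param seed Integer seed.
#' @return A class-balanced [feature_table()].
#' @export
smote_oversample <- function(table, k_neighbors = 5, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  stop_if_not_scalar_number(k_neighbors, "k_neighbors")
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1", call. = FALSE)
  n0 <- sum(table$labels == 0L)
  n1 <- sum(table$labels == 1L)
  if (n0 == n1) return(table)
  minority <- if (n1 < n0) 1L else 0L
  min_idx <- which(table$labels == minority)
  m <- length(min_idx)
  if (m < 2L) {
    stop(sprintf("SMOTE error: minority class %d has only %d row(s)",
                 minority, m), call. = FALSE)
  }
  if (k_neighbors >= m) {
    warning(sprintf("k_neighbors reduced from %d to %d (minority size %d)",
                    k_neighbors, m - 1L, m))
    k_neighbors <- m - 1L
  }
  deficit <- abs(n0 - n1)
  X <- table$features[min_idx, , drop = FALSE]
  # k nearest minority neighbors of each minority row (self excluded)
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]),
               nrow = m, ncol = k_neighbors, byrow = TRUE)
  synth <- with_seed(seed, {
    seed_order <- sample.int(m)                 # round-robin order
    out <- matrix(0, nrow = deficit, ncol = ncol(X))
    for (s in seq_len(deficit)) {
      i <- seed_order[((s - 1L) %% m) + 1L]
      j <- nn[i, sample.int(k_neighbors, 1L)]
      lambda <- stats::runif(1)
      out[s, ] <- X[i, ] + lambda * (X[j, ] - X[i, ])
    }
    out
  })
  feature_table(rbind(table$features, synth),
                c(table$labels, rep(minority, deficit)))
}
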