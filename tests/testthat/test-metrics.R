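# Confusion counts, scalar metrics, ROC/AUC, Pearson matrix, histograms.

test_that("confusion counts match a brute-force tally", {
  cm <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]), c(tp = 2, fp = 0, tn = 1, fn = 0))
  cm2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(unlist(cm2[c("tp", "fp", "tn", "fn")]), c(tp = 0, fp = 1, tn = 0, fn = 1))

  set.seed(10)
  y <- stats::rbinom(100, 1, 0.4); p <- stats::rbinom(100, 1, 0.5)
  cm3 <- confusion(y, p)
  tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in 1:100) {
    key <- if (y[i] == 1 && p[i] == 1) "tp" else if (y[i] == 0 && p[i] == 1) "fp"
      else if (y[i] == 0 && p[i] == 0) "tn" else "fn"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(cm3[c("tp", "fp", "tn", "fn")]), tally)
  expect_error(confusion(c(1, 0), c(1)), "dimension")
})

test_that("scalar metrics match hand arithmetic and conventions", {
  cm <- structure(list(tp = 50L, fp = 10L, tn = 30L, fn = 10L),
                  class = "confusion_matrix")
  m <- scalar_metrics(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(m$recall, 50 / 60, tolerance = 1e-12)
  expect_equal(m$f1, 50 / 60, tolerance = 1e-12)
  expect_equal(m$fpr, 0.25)

  # never-positive classifier: precision 0 by convention, with a warning
  cm0 <- structure(list(tp = 0L, fp = 0L, tn = 5L, fn = 3L),
                   class = "confusion_matrix")
  expect_warning(m0 <- scalar_metrics(cm0), "precision")
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)

  perfect <- scalar_metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_equal(perfect$fpr, 0)
})

test_that("scalar metrics agree with brute-force recomputation on random cases", {
  set.seed(77)
  for (case in 1:100) {
    n <- sample(5:60, 1)
    y <- stats::rbinom(n, 1, 0.5); p <- stats::rbinom(n, 1, 0.5)
    m <- suppressWarnings(scalar_metrics(confusion(y, p)))
    tp <- sum(y & p); fp <- sum(!y & p); tn <- sum(!y & !p); fn <- sum(y & !p)
    expect_equal(m$accuracy, (tp + tn) / n)
    expect_equal(m$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_equal(m$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
    expect_equal(m$fpr, if (tn + fp == 0) 0 else fp / (tn + fp))
  }
})

# Independent oracle: Mann-Whitney statistic with half ties.
mann_whitney_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))$auc, 0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)

  set.seed(123)
  for (case in 1:100) {
    n <- sample(6:40, 1)
    y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))   # both classes guaranteed
    s <- round(stats::runif(n), sample(1:3, 1))  # rounding forces ties
    r <- roc_auc(y, s)
    expect_equal(r$auc, mann_whitney_auc(y, s), tolerance = 1e-12)
    expect_equal(r$roc_points[1, ], c(fpr = 0, tpr = 0))
    expect_equal(r$roc_points[nrow(r$roc_points), ], c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$roc_points[, "fpr"]) >= 0))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("trapezoidal AUC agrees with pROC on a sample problem", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- stats::rbinom(200, 1, 0.4)
  s <- stats::runif(200) + 0.5 * y
  ours <- roc_auc(y, s)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("pearson matrix is symmetric with unit diagonal and matches the formula", {
  tab <- generate_table(synthetic_spec(n_rows = 300, prevalence = 0.35,
                                       effect_size = 2, seed = 21))
  r <- pearson_matrix(tab)
  expect_equal(dim(r), c(9, 9))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 9))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))

  # hand evaluation of the correlation formula for one pair
  x <- tab$features[, "Glucose"]; y <- as.numeric(tab$labels)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["Glucose", "Outcome"], hand, tolerance = 1e-12)
  # the shifted columns should correlate positively with the label
  expect_gt(r["Glucose", "Outcome"], 0.3)

  # simple pairs: corr(x, x) = 1, corr(x, -x) = -1 via the same formula
  x3 <- c(1, 2, 3); y3 <- c(2, 4, 6.5)
  hand3 <- sum((x3 - 2) * (y3 - mean(y3))) /
    sqrt(sum((x3 - 2)^2) * sum((y3 - mean(y3))^2))
  expect_equal(hand3, stats::cor(x3, y3), tolerance = 1e-12)
  expect_equal(hand3, 0.99795, tolerance = 1e-4)

  tab$features[, "Pregnancies"] <- 1
  expect_warning(r2 <- pearson_matrix(tab), "constant")
  expect_true(is.na(r2["Pregnancies", "Glucose"]))
})

test_that("histogram counts partition the data across equal-width bins", {
  h <- histogram_counts(c(0, 1), 2)
  expect_equal(h$counts, c(1L, 1L))
  expect_equal(h$bin_edges, c(0, 0.5, 1))

  hd <- histogram_counts(rep(3.2, 10), 4)
  expect_equal(sum(hd$counts), 10)
  expect_equal(hd$counts, 10L)

  set.seed(9)
  u <- stats::runif(1e4)
  h10 <- histogram_counts(u, 10)
  expect_equal(sum(h10$counts), 1e4)
  sd_bin <- sqrt(1e4 * 0.1 * 0.9)
  expect_true(all(abs(h10$counts - 1e3) <= 5 * sd_bin))
  # right-most bin is closed: the maximum is counted
  hmax <- histogram_counts(c(0, 0.5, 1), 2)
  expect_equal(sum(hmax$counts), 3)
  expect_error(histogram_counts(numeric(0), 3), "non-empty")
})
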