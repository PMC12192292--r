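# Imputation, normalization, stratified splitting, SMOTE.

test_that("zero-as-missing imputation replaces zeros by the nonzero mean", {
  feats <- matrix(rep(c(1, 100, 70, 20, 0, 30, 0.5, 25), each = 3), 3, 8)
  feats[, 5] <- c(0, 2, 4)
  tab <- feature_table(feats, c(0, 1, 0))
  out <- impute_zero_as_missing_mean(tab, "Insulin")
  expect_equal(unname(out$features[, "Insulin"]), c(3, 2, 4))  # mean{2,4} = 3
  # untouched columns and the nonzero entries are preserved
  expect_identical(out$features[, "Glucose"], tab$features[, "Glucose"])
  nz <- tab$features[, "Insulin"] != 0
  expect_identical(out$features[nz, "Insulin"], tab$features[nz, "Insulin"])
})

test_that("imputation edge cases: no zeros, empty column list, all-zero column", {
  tab <- small_table()
  expect_identical(impute_zero_as_missing_mean(tab, "Glucose"), tab)
  expect_identical(impute_zero_as_missing_mean(tab, character(0)), tab)
  tab$features[, "Insulin"] <- 0
  expect_error(impute_zero_as_missing_mean(tab, "Insulin"), "Insulin")
})

test_that("min-max model records exact per-column extrema", {
  tab <- small_table()
  model <- fit_minmax(tab)
  for (j in seq_len(8)) {
    expect_identical(unname(model$x_min[j]), min(tab$features[, j]))
    expect_identical(unname(model$x_max[j]), max(tab$features[, j]))
  }
  expect_error(fit_minmax(feature_table(matrix(numeric(0), ncol = 8),
                                        integer(0))),
               "empty")
})

test_that("normalization rescales into [0,1] on the fitting table", {
  tab <- small_table()
  model <- fit_minmax(tab)
  out <- apply_minmax(tab, model)
  expect_true(all(out$features >= 0 & out$features <= 1))
  # endpoints map to 0 and 1
  expect_equal(min(out$features[, "Glucose"]), 0)
  expect_equal(max(out$features[, "Glucose"]), 1)
  # hand case: column [2,4,6] -> [0, 0.5, 1]
  x <- (c(2, 4, 6) - 2) / (6 - 2)
  expect_equal(x, c(0, 0.5, 1))
  # a constant column maps to 0 with a warning
  tab2 <- small_table()
  tab2$features[, "Pregnancies"] <- 5
  m2 <- fit_minmax(tab2)
  expect_warning(out2 <- apply_minmax(tab2, m2), "constant")
  expect_true(all(out2$features[, "Pregnancies"] == 0))
})

test_that("train-set model applied to test data can exceed [0,1]", {
  tab <- small_table()
  model <- fit_minmax(tab)
  wider <- tab
  wider$features[1, "Glucose"] <- 300   # beyond the fitted max
  out <- apply_minmax(wider, model)
  expect_gt(out$features[1, "Glucose"], 1)
})

test_that("stratified split honours largest-remainder class counts", {
  tab <- generate_table(synthetic_spec(n_rows = 100, prevalence = 0.35,
                                       effect_size = 1, seed = 8))
  # quantile labelling gives exactly 35 positives here
  expect_equal(sum(tab$labels), 35)
  sp <- stratified_split(tab, 0.8, seed = 2)
  expect_equal(sum(sp$train$labels == 0L), 52)
  expect_equal(sum(sp$train$labels == 1L), 28)
  expect_equal(n_rows(sp$train), 80)
  expect_equal(n_rows(sp$test), 20)

  tab769 <- generate_table(synthetic_spec(n_rows = 769, prevalence = 0.35,
                                          effect_size = 1, seed = 8))
  sp769 <- stratified_split(tab769, 0.8, seed = 2)
  expect_equal(n_rows(sp769$train), 615)
  expect_equal(n_rows(sp769$test), 154)
})

test_that("split parts reassemble the input exactly and are seed-stable", {
  tab <- generate_table(synthetic_spec(n_rows = 123, prevalence = 0.4,
                                       effect_size = 1, seed = 3))
  sp1 <- stratified_split(tab, 0.8, seed = 7)
  sp2 <- stratified_split(tab, 0.8, seed = 7)
  expect_identical(sp1, sp2)
  sp3 <- stratified_split(tab, 0.8, seed = 8)
  expect_false(identical(sp1$train, sp3$train))
  # union as a multiset of rows equals the input
  all_rows <- rbind(sp1$train$features, sp1$test$features)
  key <- function(m) sort(apply(m, 1, paste, collapse = "|"))
  expect_identical(key(all_rows), key(tab$features))
  expect_equal(sort(c(sp1$train$labels, sp1$test$labels)), sort(tab$labels))
})

test_that("split rejects degenerate inputs", {
  tab <- small_table()
  expect_error(stratified_split(tab, 1.2), "train_fraction")
  one_pos <- feature_table(tab$features, c(1, rep(0, 9)))
  expect_error(stratified_split(one_pos, 0.8), "stratification")
})

test_that("SMOTE balances classes, keeps originals first and unchanged", {
  tab <- small_table()   # 6 positive / 4 negative
  out <- smote_oversample(tab, k_neighbors = 2, seed = 1)
  expect_equal(sum(out$labels == 0L), sum(out$labels == 1L))
  expect_identical(out$features[1:10, ], tab$features)
  expect_identical(out$labels[1:10], tab$labels)
  # synthetic rows carry the minority label
  expect_true(all(out$labels[11:n_rows(out)] == 0L))
  # determinism
  expect_identical(out, smote_oversample(tab, k_neighbors = 2, seed = 1))
})

test_that("SMOTE degenerate cases behave as documented", {
  tab <- small_table()
  balanced <- feature_table(tab$features, rep(c(0, 1), 5))
  expect_identical(smote_oversample(balanced, 3, 1), balanced)

  # single-row minority is an error
  solo <- feature_table(tab$features, c(1, rep(0, 9)))
  expect_error(smote_oversample(solo, 3, 1), "minority")

  # identical minority rows: every synthetic point equals that point
  dup <- tab
  dup$features[tab$labels == 0L, ] <- rep(tab$features[2, ], each = 4)
  out <- smote_oversample(dup, 2, 1)
  synth <- out$features[11:n_rows(out), , drop = FALSE]
  expect_true(all(apply(synth, 1, function(r) all(r == tab$features[2, ]))))

  # oversized k is capped with a warning
  expect_warning(smote_oversample(tab, k_neighbors = 10, seed = 1),
                 "k_neighbors reduced")
})

test_that("every synthetic row is a convex combination of seed and neighbor", {
  tab <- generate_table(synthetic_spec(n_rows = 1600, prevalence = 0.2,
                                       effect_size = 1, seed = 13))
  out <- smote_oversample(tab, 5, seed = 2)
  n_orig <- n_rows(tab)
  deficit <- sum(tab$labels == 0L) - sum(tab$labels == 1L)
  synth <- out$features[(n_orig + 1):n_rows(out), , drop = FALSE]
  expect_equal(nrow(synth), deficit)
  expect_gt(nrow(synth), 900)
  minority <- tab$features[tab$labels == 1L, , drop = FALSE]
  lo <- apply(minority, 2, min); hi <- apply(minority, 2, max)
  # each synthetic row lies inside the minority bounding box (necessary
  # consequence of interpolation between minority points)
  for (j in seq_len(8)) {
    expect_true(all(synth[, j] >= lo[j] - 1e-12 & synth[, j] <= hi[j] + 1e-12))
  }
})
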