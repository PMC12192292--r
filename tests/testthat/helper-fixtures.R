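# Fixtures built in code: a small handwritten table and a preprocessed
# synthetic classification task.

# Deterministic 10-row table with both classes and a zero in each
# missingness-prone column.
small_table <- function() {
  feats <- rbind(
    c(1, 148, 72, 35, 155, 33.6, 0.627, 50),
    c(0,  85, 66, 29, 120, 26.6, 0.351, 31),
    c(8, 183, 64,  0, 230, 23.3, 0.672, 32),
    c(1,  89,  0, 23,  94, 28.1, 0.167, 21),
    c(0, 137, 40, 35, 168, 43.1, 2.288, 33),
    c(5, 116, 74,  0,   0, 25.6, 0.201, 30),
    c(3,  78, 50, 32,  88, 31.0, 0.248, 26),
    c(2, 197, 70, 45, 543, 30.5, 0.158, 53),
    c(4, 110, 92,  0,   0, 37.6, 0.191, 30),
    c(10, 168, 74,  0,   0, 38.0, 0.537, 34))
  feature_table(feats, c(1, 0, 1, 0, 1, 0, 1, 1, 0, 1))
}

# Fully preprocessed train/test pair from the synthetic generator.
make_task <- function(seed, n = 500, effect = 3, smote = TRUE) {
  tab <- generate_table(synthetic_spec(n_rows = n, prevalence = 0.35,
                                       effect_size = effect, seed = seed))
  tab <- impute_zero_as_missing_mean(tab)
  sp <- stratified_split(tab, 0.8, seed)
  train <- if (smote) smote_oversample(sp$train, 5, seed) else sp$train
  norm <- fit_minmax(train)
  list(train = apply_minmax(train, norm),
       test = apply_minmax(sp$test, norm),
       norm = norm)
}

golden <- (sqrt(5) - 1) / 2
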