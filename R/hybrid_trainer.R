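# Hybrid IRSA-BP training: the metaheuristic searches the flat weight space
# for a low-training-error starting point, then plain backpropagation
# refines it.

#' Classification-error fitness of a flat weight vector
#'
#' The objective the optimizer minimizes: decode the candidate into network
#' parameters, predict the training labels, and return
#' `1 - (correct / n)` (a value in `[0, 1]`).
#'
#' @param flat Flat parameter vector of length `param_count(spec)`.
#' @param spec A [network_spec()].
#' @param features Training feature matrix (already normalized).
#' @param labels Training 0/1 labels.
#' @return Misclassification rate in `[0, 1]`.
#' @export
classification_fitness <- function(flat, spec, features, labels) {
  pred <- nn_predict(decode_params(flat, spec), spec, features)
  1 - mean(pred == as.integer(labels))
}

#' Train a network with IRSA (or RSA) followed by backpropagation
#'
#' Stage 1: [rsa_optimize()] searches the flat weight/bias space (box
#' `[-3, 3]` per dimension by default) minimizing
#' [classification_fitness()] on the training table. Stage 2: the best
#' vector found seeds [backprop_train()] on the same table. Setting
#' `bp_cfg$epochs = 0` disables refinement and returns the decoded optimizer
#' solution unchanged.
#'
#' @param train A preprocessed (normalized) [feature_table()].
#' @param net_spec A [network_spec()]; its input width must be 8.
#' @param opt_cfg An [irsa_config()] (its `seed` drives the whole search).
#' @param bp_cfg A [train_config()].
#' @param variant `"irsa"` (default) or `"rsa"`.
#' @param bounds Length-2 numeric: search box per dimension. Default
#'   `c(-3, 3)`.
#' @param normalization Optional `minmax_model` to store with the model for
#'   serialization.
#' @return An object of class `trained_model`: `params`, `spec`,
#'   `normalization`, `search_history` (best fitness per optimizer
#'   iteration, non-increasing), `refine_history` (MSE per epoch) and
#'   `variant`.
#' @export
train_irsa_bp <- function(train, net_spec = network_spec(),
                          opt_cfg = irsa_config(), bp_cfg = train_config(),
                          variant = c("irsa", "rsa"), bounds = c(-3, 3),
                          normalization = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(train, "feature_table"), inherits(net_spec, "network_spec"))
  if (net_spec$layer_sizes[1L] != ncol(train$features)) {
    stop(sprintf("network input width %d does not match %d feature columns",
                 net_spec$layer_sizes[1L], ncol(train$features)), call. = FALSE)
  }
  d <- param_count(net_spec)
  space <- search_space(bounds[1L], bounds[2L], dim = d)
  objective <- function(flat) {
    classification_fitness(flat, net_spec, train$features, train$labels)
  }
  state <- rsa_optimize(objective, space, opt_cfg, variant)
  params <- decode_params(state$best_position, net_spec)
  refine_history <- numeric(0)
  if (bp_cfg$epochs > 0L) {
    params <- backprop_train(params, net_spec, train$features,
                             one_hot(train$labels), bp_cfg)
    refine_history <- attr(params, "loss_history")
    attr(params, "loss_history") <- NULL
  }
  structure(list(params = params, spec = net_spec,
                 normalization = normalization,
                 search_history = state$history,
                 refine_history = refine_history,
                 variant = variant),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, layers [%s], search best %.4f, %d refinement epochs\n",
              x$variant, paste(x$spec$layer_sizes, collapse = ", "),
              min(x$search_history),
              max(length(x$refine_history) - 1L, 0L)))
  invisible(x)
}

#' Evaluate a trained model on a feature table
#'
#' @param model A `trained_model`.
#' @param table A normalized [feature_table()].
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, table) {
  stopifnot(inherits(model, "trained_model"), inherits(table, "feature_table"))
  pred <- nn_predict(model$params, model$spec, table$features)
  scores <- nn_score(model$params, model$spec, table$features)
  metrics_report(table$labels, pred, scores)
}

#' Compare optimizer variants over repeated seeded runs
#'
#' Trains one model per (variant, seed) on `train`, evaluates every model
#' on `test`, and reports the per-variant mean and standard deviation of
#' accuracy, AUC, precision, recall and F1.
#'
#' @param train,test Normalized [feature_table()]s.
#' @param net_spec A [network_spec()].
#' @param opt_cfg An [irsa_config()]; its seed field is replaced by each run
#'   seed.
#' @param bp_cfg A [train_config()].
#' @param variants Character vector drawn from `c("irsa", "rsa")`.
#' @param n_seeds Number of seeded repetitions (>= 1); run seeds are
#'   `seed_base + 1:n_seeds`.
#' @param seed_base Offset for the run seeds. Default 0.
#' @return A data frame with one row per variant: `variant`, `n_seeds`,
#'   and `<metric>_mean` / `<metric>_sd` columns for the five metrics.
#' @export
compare_optimizers <- function(train, test, net_spec = network_spec(),
                               opt_cfg = irsa_config(),
                               bp_cfg = train_config(),
                               variants = c("irsa", "rsa"), n_seeds = 10,
                               seed_base = 0) {
  n_seeds <- as.integer(n_seeds)
  if (n_seeds < 1L) stop("n_seeds must be >= 1", call. = FALSE)
  metric_names <- c("accuracy", "auc", "precision", "recall", "f1")
  rows <- lapply(variants, function(v) {
    per_seed <- vapply(seq_len(n_seeds), function(s) {
      cfg <- opt_cfg
      cfg$seed <- as.integer(seed_base + s)
      model <- train_irsa_bp(train, net_spec, cfg, bp_cfg, variant = v)
      rep <- evaluate_model(model, test)
      unlist(rep[metric_names])
    }, numeric(length(metric_names)))
    per_seed <- matrix(per_seed, nrow = length(metric_names))
    means <- rowMeans(per_seed)
    sds <- apply(per_seed, 1, stats::sd)
    if (n_seeds == 1L) sds <- rep(0, length(metric_names))
    row <- data.frame(variant = v, n_seeds = n_seeds)
    for (k in seq_along(metric_names)) {
      row[[paste0(metric_names[k], "_mean")]] <- means[k]
      row[[paste0(metric_names[k], "_sd")]] <- sds[k]
    }
    row
  })
  do.call(rbind, rows)
}
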