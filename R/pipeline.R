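# End-to-end pipeline: simulate/load -> impute -> split -> SMOTE ->
# normalize -> IRSA-BP train -> evaluate, driven by a flat YAML config and
# four independent seeds (data / split / smote / optimizer) so each
# stochastic stage is replayable on its own.

#' Default run configuration
#'
#' Nested list understood by [run_pipeline()] and [validate_config()].
#' Sections: `data` (synthetic spec or `path` to a CSV), `preprocessing`
#' (impute columns, split fraction, SMOTE scope/k, normalization scope),
#' `network`, `optimizer`, `bp`, `seeds`, `output` (directory for
#' artifacts).
#'
#' @param out_dir Output directory for artifacts.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("irsabp-run-")) {
  structure(list(
    data = list(path = NULL, n_rows = 769, prevalence = 0.35,
                effect_size = 1.5, zero_inflation = c(0.05, 0.30, 0.49)),
    preprocessing = list(
      impute_columns = c("Blood Pressure", "Skin Thickness", "Insulin"),
      train_fraction = 0.8,
      smote_scope = "train",       # "train", "full" or "none"
      k_neighbors = 5,
      normalize_on = "train"),     # "train" or "full"
    network = list(layer_sizes = c(8, 8, 2), hidden_activation = "sigmoid"),
    optimizer = list(variant = "irsa", n_pop = 10, max_iter = 8,
                     alpha = 0.1, beta = 0.1, epsilon = 1e-10, xi = 1e-6,
                     lower = -3, upper = 3,
                     chaos_c0 = 0.3, chaos_mu = 2.595),
    bp = list(learning_rate = 0.01, epochs = 10000),
    seeds = list(data = 1, split = 2, smote = 3, optimizer = 4),
    output = list(dir = out_dir)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults from
#' [default_run_config()]; unknown keys are reported by
#' [validate_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (section in names(user)) {
    if (is.list(user[[section]]) && section %in% names(cfg)) {
      for (key in names(user[[section]])) {
        cfg[[section]][[key]] <- user[[section]][[key]]
      }
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

#' Validate a run configuration
#'
#' Checks every module precondition that can be verified before execution.
#'
#' @param config A `run_config` list.
#' @return Character vector of violations (empty when the config is valid);
#'   each entry names the offending key and the violated constraint.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  known <- names(default_run_config())
  extra <- setdiff(names(config), known)
  if (length(extra)) add(sprintf("unknown section(s): %s", paste(extra, collapse = ", ")))

  d <- config$data
  if (is.null(d$path)) {
    if (!is.null(d$n_rows) && d$n_rows < 10) add("data.n_rows: must be >= 10")
    if (!is.null(d$prevalence) && (d$prevalence <= 0 || d$prevalence >= 1))
      add("data.prevalence: must lie strictly in (0, 1)")
    if (!is.null(d$effect_size) && d$effect_size < 0)
      add("data.effect_size: must be >= 0")
    zi <- d$zero_inflation
    if (!is.null(zi) && (length(zi) != 3 || any(zi < 0) || any(zi >= 1)))
      add("data.zero_inflation: three probabilities in [0, 1)")
  }
  p <- config$preprocessing
  if (!is.null(p$train_fraction) && (p$train_fraction <= 0 || p$train_fraction >= 1))
    add("preprocessing.train_fraction: must lie strictly in (0, 1)")
  if (!is.null(p$smote_scope) && !p$smote_scope %in% c("train", "full", "none"))
    add("preprocessing.smote_scope: one of train, full, none")
  if (!is.null(p$k_neighbors) && p$k_neighbors < 1)
    add("preprocessing.k_neighbors: must be >= 1")
  if (!is.null(p$normalize_on) && !p$normalize_on %in% c("train", "full"))
    add("preprocessing.normalize_on: one of train, full")
  if (!is.null(p$impute_columns) &&
      !all(p$impute_columns %in% pima_feature_names()))
    add("preprocessing.impute_columns: unknown feature name")

  net <- config$network
  if (!is.null(net$layer_sizes)) {
    if (length(net$layer_sizes) < 3 || any(net$layer_sizes < 1))
      add("network.layer_sizes: needs >= 3 positive entries")
    else if (net$layer_sizes[1] != 8)
      add("network.layer_sizes: input layer must have 8 nodes")
    else if (net$layer_sizes[length(net$layer_sizes)] != 2)
      add("network.layer_sizes: output layer must have 2 nodes")
  }
  o <- config$optimizer
  if (!is.null(o$variant) && !o$variant %in% c("irsa", "rsa"))
    add("optimizer.variant: one of irsa, rsa")
  if (!is.null(o$n_pop) && o$n_pop < 2) add("optimizer.n_pop: must be >= 2 (N >= 2)")
  if (!is.null(o$max_iter) && o$max_iter < 1) add("optimizer.max_iter: must be >= 1")
  if (!is.null(o$epsilon) && o$epsilon <= 0) add("optimizer.epsilon: must be > 0")
  if (!is.null(o$xi) && o$xi <= 0) add("optimizer.xi: must be > 0")
  if (!is.null(o$lower) && !is.null(o$upper) && o$lower >= o$upper)
    add("optimizer.lower/upper: lower must be < upper")
  if (!is.null(o$chaos_c0) && (o$chaos_c0 <= 0 || o$chaos_c0 >= 1))
    add("optimizer.chaos_c0: must lie strictly in (0, 1)")
  b <- config$bp
  if (!is.null(b$learning_rate) && b$learning_rate <= 0)
    add("bp.learning_rate: must be > 0")
  if (!is.null(b$epochs) && b$epochs < 0) add("bp.epochs: must be >= 0")
  s <- config$seeds
  for (k in c("data", "split", "smote", "optimizer")) {
    if (!is.null(s[[k]]) && (!is.numeric(s[[k]]) || s[[k]] != round(s[[k]])))
      add(sprintf("seeds.%s: must be an integer", k))
  }
  v
}

pipeline_log <- function(con, level, stage, msg) {
  writeLines(sprintf("%s [%s] (%s) %s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     level, stage, msg), con)
}

#' Run the full training pipeline
#'
#' Executes the configured stages in order (simulate or load CSV, impute
#' zeros, stratified split, optional SMOTE, min-max normalization, IRSA-BP
#' training, evaluation) and writes five artifacts into
#' `config$output$dir`: `train.csv`, `test.csv`, `model.txt`,
#' `metrics.json` and `run.log`. Re-running with the same config reproduces
#' every artifact byte-for-byte except the timestamps inside the log.
#'
#' @param config A `run_config` list (see [default_run_config()]), or the
#'   path to a YAML file.
#' @return Invisibly, a list with the `trained_model`, the test-set
#'   [metrics_report()], and the artifact paths.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- validate_config(config)
  if (length(problems)) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)

  stage <- "data"
  result <- tryCatch({
    tab <- if (!is.null(config$data$path)) {
      pipeline_log(con, "INFO", stage, sprintf("reading %s", config$data$path))
      read_feature_csv(config$data$path)
    } else {
      pipeline_log(con, "INFO", stage,
                   sprintf("simulating n=%d prevalence=%.2f effect=%.2f",
                           config$data$n_rows, config$data$prevalence,
                           config$data$effect_size))
      generate_table(synthetic_spec(
        n_rows = config$data$n_rows, prevalence = config$data$prevalence,
        effect_size = config$data$effect_size,
        zero_inflation = config$data$zero_inflation,
        seed = config$seeds$data))
    }

    stage <- "impute"
    tab <- impute_zero_as_missing_mean(tab, config$preprocessing$impute_columns)

    stage <- "smote-full"
    if (identical(config$preprocessing$smote_scope, "full")) {
      tab <- smote_oversample(tab, config$preprocessing$k_neighbors,
                              config$seeds$smote)
      pipeline_log(con, "INFO", stage, sprintf("balanced to %d rows", n_rows(tab)))
    }

    stage <- "split"
    sp <- stratified_split(tab, config$preprocessing$train_fraction,
                           config$seeds$split)
    train <- sp$train; test <- sp$test
    pipeline_log(con, "INFO", stage,
                 sprintf("train %d rows / test %d rows", n_rows(train), n_rows(test)))

    stage <- "smote-train"
    if (identical(config$preprocessing$smote_scope, "train")) {
      train <- smote_oversample(train, config$preprocessing$k_neighbors,
                                config$seeds$smote)
      pipeline_log(con, "INFO", stage,
                   sprintf("training set balanced to %d rows", n_rows(train)))
    }

    stage <- "normalize"
    norm_src <- if (identical(config$preprocessing$normalize_on, "full")) tab else train
    norm <- fit_minmax(norm_src)
    train_n <- apply_minmax(train, norm)
    test_n <- apply_minmax(test, norm)

    stage <- "train"
    opt_cfg <- irsa_config(
      n_pop = config$optimizer$n_pop, max_iter = config$optimizer$max_iter,
      alpha = config$optimizer$alpha, beta = config$optimizer$beta,
      epsilon = config$optimizer$epsilon, xi = config$optimizer$xi,
      seed = config$seeds$optimizer,
      chaos = chaos_params(config$optimizer$chaos_c0, config$optimizer$chaos_mu))
    net_spec <- network_spec(config$network$layer_sizes,
                             config$network$hidden_activation)
    bp_cfg <- train_config(config$bp$learning_rate, config$bp$epochs)
    model <- train_irsa_bp(train_n, net_spec, opt_cfg, bp_cfg,
                           variant = config$optimizer$variant,
                           bounds = c(config$optimizer$lower,
                                      config$optimizer$upper),
                           normalization = norm)
    for (k in seq_along(model$search_history)) {
      pipeline_log(con, "DEBUG", stage,
                   sprintf("iteration %d best fitness %.6f",
                           k, model$search_history[k]))
    }

    stage <- "evaluate"
    report <- evaluate_model(model, test_n)
    pipeline_log(con, "INFO", stage,
                 sprintf("test accuracy %.4f auc %.4f", report$accuracy,
                         report$auc))

    stage <- "write"
    paths <- list(train = file.path(out_dir, "train.csv"),
                  test = file.path(out_dir, "test.csv"),
                  model = file.path(out_dir, "model.txt"),
                  metrics = file.path(out_dir, "metrics.json"),
                  log = log_path)
    write_feature_csv(train_n, paths$train)
    write_feature_csv(test_n, paths$test)
    write_model(model, paths$model)
    jsonlite::write_json(
      list(accuracy = report$accuracy, precision = report$precision,
           recall = report$recall, f1 = report$f1, fpr = report$fpr,
           auc = report$auc,
           search_history = model$search_history,
           config = config[setdiff(names(config), "output")]),
      paths$metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(model = model, report = report, paths = paths)
  }, error = function(e) {
    pipeline_log(con, "ERROR", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
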