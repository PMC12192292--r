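# Feed-forward network trained by backpropagation, with the canonical flat
# weight/bias encoding the optimizer searches over.

#' Network architecture specification
#'
#' @param layer_sizes Ordered integer vector of layer widths; at least 3
#'   entries (input, >= 1 hidden, output). Default `c(8, 8, 2)`: one node
#'   per clinical feature, 8 hidden nodes, one output node per class.
#' @param hidden_activation `"sigmoid"` (default) or `"relu"`.
#' @param output_activation `"sigmoid"` only.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(layer_sizes = c(8, 8, 2),
                         hidden_activation = c("sigmoid", "relu"),
                         output_activation = "sigmoid") {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation, "sigmoid")
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 3L || any(layer_sizes < 1L)) {
    stop("layer_sizes needs >= 3 positive entries (input, hidden..., output)",
         call. = FALSE)
  }
  structure(list(layer_sizes = layer_sizes,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "network_spec")
}

#' Total number of weights and biases
#'
#' Sums `fan_in * fan_out + fan_out` over consecutive layer pairs; this is
#' the dimension of the optimizer's search space.
#'
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
#' @examples
#' param_count(network_spec(c(8, 8, 2)))
param_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- spec$layer_sizes
  n <- length(sizes)
  sum(sizes[-n] * sizes[-1L] + sizes[-1L])
}

#' Decode a flat vector into layered weights and biases
#'
#' Canonical order: for each consecutive layer pair in order, the weight
#' matrix row-major by source node then destination node, followed by that
#' layer's biases. `encode_params()` inverts it exactly.
#'
#' @param flat Numeric vector of length `param_count(spec)`.
#' @param spec A [network_spec()].
#' @return An object of class `network_params`: list of layers, each with a
#'   `w` (fan_in x fan_out) matrix and `b` (fan_out) vector.
#' @export
decode_params <- function(flat, spec) {
  stopifnot(inherits(spec, "network_spec"))
  expected <- param_count(spec)
  if (length(flat) != expected) {
    stop(sprintf("dimension error: expected a flat vector of length %d, got %d",
                 expected, length(flat)), call. = FALSE)
  }
  sizes <- spec$layer_sizes
  layers <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (l in seq_along(layers)) {
    fi <- sizes[l]; fo <- sizes[l + 1L]
    w <- matrix(flat[pos + seq_len(fi * fo)], nrow = fi, ncol = fo,
                byrow = TRUE)
    pos <- pos + fi * fo
    b <- flat[pos + seq_len(fo)]
    pos <- pos + fo
    layers[[l]] <- list(w = w, b = b)
  }
  structure(layers, class = "network_params")
}

#' @rdname decode_params
#' @param params A `network_params` object.
#' @export
encode_params <- function(params) {
  stopifnot(inherits(params, "network_params"))
  unlist(lapply(unclass(params), function(layer) {
    c(as.vector(t(layer$w)), layer$b)
  }), use.names = FALSE)
}

activation_fn <- function(name) {
  switch(name,
         sigmoid = sigmoid,
         relu = function(z) pmax(z, 0),
         stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# Derivative of the activation as a function of the *pre-activation*.
activation_grad <- function(name) {
  switch(name,
         sigmoid = function(z) { s <- sigmoid(z); s * (1 - s) },
         relu = function(z) as.numeric(z > 0),
         stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# Forward pass keeping pre-activations and activations per layer (for
# backprop). X: n x features.
forward_full <- function(params, spec, X) {
  acts <- list(X)
  pre <- list()
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% params[[l]]$w +
      matrix(params[[l]]$b, nrow = nrow(X), ncol = length(params[[l]]$b),
             byrow = TRUE)
    act_name <- if (l == n_layers) spec$output_activation else spec$hidden_activation
    pre[[l]] <- z
    acts[[l + 1L]] <- activation_fn(act_name)(z)
  }
  list(pre = pre, acts = acts)
}

#' Forward pass
#'
#' Propagates a matrix of observations through the network:
#' `h = f(X W + b)` layer by layer.
#'
#' @param params A `network_params` from [decode_params()].
#' @param spec The matching [network_spec()].
#' @param X Numeric matrix, one row per observation, columns = input layer
#'   width.
#' @return Matrix of output activations, `nrow(X)` x output width; values in
#'   (0, 1) for the sigmoid output.
#' @export
nn_forward <- function(params, spec, X) {
  stopifnot(inherits(params, "network_params"), inherits(spec, "network_spec"))
  X <- as.matrix(X)
  if (ncol(X) != spec$layer_sizes[1L]) {
    stop(sprintf("dimension error: expected %d input columns, got %d",
                 spec$layer_sizes[1L], ncol(X)), call. = FALSE)
  }
  if (length(X) && !all(is.finite(X))) {
    stop("input matrix contains non-finite values", call. = FALSE)
  }
  forward_full(params, spec, X)$acts[[length(params) + 1L]]
}

#' Predict binary labels
#'
#' With one output node per class, the predicted label is the index of the
#' larger output (node 1 -> label 0, node 2 -> label 1); exact ties resolve
#' to label 0.
#'
#' @inheritParams nn_forward
#' @return Integer vector of 0/1 labels.
#' @export
nn_predict <- function(params, spec, X) {
  out <- nn_forward(params, spec, X)
  as.integer(out[, 2L] > out[, 1L])
}

#' Class-1 score for ROC analysis
#'
#' The second (class-1) output node's activation, used as the ranking score
#' for ROC/AUC computation.
#'
#' @inheritParams nn_forward
#' @return Numeric vector of scores in (0, 1).
#' @export
nn_score <- function(params, spec, X) nn_forward(params, spec, X)[, 2L]

#' One-hot encode 0/1 labels
#'
#' Label 0 -> `(1, 0)`, label 1 -> `(0, 1)`.
#'
#' @param labels Vector of 0/1 labels.
#' @return Matrix with `length(labels)` rows and 2 columns.
#' @export
one_hot <- function(labels) {
  labels <- as.integer(labels)
  cbind(1 - labels, labels)
}

#' Backpropagation training configuration
#'
#' @param learning_rate Gradient step size (> 0). Default 0.01.
#' @param epochs Number of full-batch epochs. Default 10000.
#' @param loss Only `"mse"`.
#' @param patience Early-stop window: training halts when the MSE improves
#'   by less than `min_delta` over `patience` epochs. Default 100.
#' @param min_delta Early-stop improvement threshold. Default 1e-12.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 10000, loss = "mse",
                         patience = 100, min_delta = 1e-12) {
  loss <- match.arg(loss, "mse")
  stop_if_not_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  epochs <- as.integer(epochs)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = epochs, loss = loss,
                 patience = as.integer(patience), min_delta = min_delta),
            class = "train_config")
}

# MSE loss and its full-batch gradient, as a flat vector in canonical order.
# Loss: (1 / (2n)) * sum((yhat - y)^2).
nn_loss_and_grad <- function(flat, spec, X, Y) {
  params <- decode_params(flat, spec)
  fw <- forward_full(params, spec, X)
  n_layers <- length(params)
  yhat <- fw$acts[[n_layers + 1L]]
  n <- nrow(X)
  resid <- yhat - Y
  loss <- sum(resid^2) / (2 * n)
  grads <- vector("list", n_layers)
  delta <- NULL
  for (l in rev(seq_len(n_layers))) {
    act_name <- if (l == n_layers) spec$output_activation else spec$hidden_activation
    fprime <- activation_grad(act_name)(fw$pre[[l]])
    if (l == n_layers) {
      delta <- (resid / n) * fprime
    } else {
      delta <- (delta %*% t(params[[l + 1L]]$w)) * fprime
    }
    grads[[l]] <- list(w = t(fw$acts[[l]]) %*% delta,
                       b = colSums(delta))
  }
  list(loss = loss,
       grad = encode_params(structure(grads, class = "network_params")),
       yhat = yhat)
}

#' Gradient of the training loss (for verification)
#'
#' Analytic full-batch gradient of the mean-squared-error loss
#' `(1/(2n)) * sum((yhat - y)^2)` with respect to the flat parameter vector,
#' in canonical encoding order.
#'
#' @param flat Flat parameter vector.
#' @param spec A [network_spec()].
#' @param X Input matrix.
#' @param y_onehot One-hot target matrix (see [one_hot()]).
#' @return List with `loss` (scalar) and `grad` (vector matching `flat`).
#' @export
nn_gradient <- function(flat, spec, X, y_onehot) {
  res <- nn_loss_and_grad(flat, spec, as.matrix(X), as.matrix(y_onehot))
  res[c("loss", "grad")]
}

#' Train a network by full-batch gradient descent
#'
#' Standard backpropagation on the squared-error loss: output deltas
#' `(yhat - y) * f'(z)` are propagated back through the weights and every
#' parameter moves against its gradient by `learning_rate`. Each epoch
#' applies the accumulated per-pattern updates in one batch step, i.e. the
#' step is `learning_rate` times the gradient of the *summed* squared error
#' `0.5 * sum((yhat - y)^2)`; the recorded loss history is the mean-scaled
#' MSE `(1/(2n)) * sum((yhat - y)^2)`, which differs only by the constant
#' factor `n`. Training stops after `cfg$epochs` epochs or earlier when the
#' loss improvement over `cfg$patience` epochs falls below `cfg$min_delta`.
#'
#' @param params Starting `network_params`.
#' @param spec The [network_spec()].
#' @param X Input matrix (rows = observations).
#' @param y_onehot One-hot target matrix.
#' @param cfg A [train_config()].
#' @return Updated `network_params`; the per-epoch loss trace is attached as
#'   attribute `"loss_history"` (first entry = loss before any update).
#' @export
backprop_train <- function(params, spec, X, y_onehot, cfg = train_config()) {
  stopifnot(inherits(params, "network_params"), inherits(spec, "network_spec"),
            inherits(cfg, "train_config"))
  X <- as.matrix(X); Y <- as.matrix(y_onehot)
  if (nrow(X) != nrow(Y)) stop("X and y_onehot row counts differ", call. = FALSE)
  flat <- encode_params(params)
  history <- numeric(cfg$epochs + 1L)
  res <- nn_loss_and_grad(flat, spec, X, Y)
  history[1L] <- res$loss
  n_done <- 0L
  n_batch <- nrow(X)
  for (epoch in seq_len(cfg$epochs)) {
    flat <- flat - cfg$learning_rate * n_batch * res$grad
    res <- nn_loss_and_grad(flat, spec, X, Y)
    if (!is.finite(res$loss)) {
      stop(sprintf("divergence error: non-finite loss at epoch %d", epoch),
           call. = FALSE)
    }
    history[epoch + 1L] <- res$loss
    n_done <- epoch
    if (epoch > cfg$patience) {
      if (history[epoch + 1L - cfg$patience] - history[epoch + 1L] < cfg$min_delta) break
    }
  }
  out <- decode_params(flat, spec)
  attr(out, "loss_history") <- history[seq_len(n_done + 1L)]
  out
}

#' Write / read a trained classifier as plain text
#'
#' Serializes the architecture, the canonical flat parameter vector, and the
#' normalization model to a JSON text file so a trained classifier
#' round-trips through disk.
#'
#' @param model A `trained_model` from [train_irsa_bp()], or a list with
#'   elements `spec`, `params`, and optionally `normalization`.
#' @param path Output path.
#' @return `path` invisibly (`write_model`); a `trained_model`-shaped list
#'   (`read_model`).
#' @export
write_model <- function(model, path) {
  payload <- list(
    layer_sizes = model$spec$layer_sizes,
    hidden_activation = model$spec$hidden_activation,
    output_activation = model$spec$output_activation,
    flat = encode_params(model$params),
    normalization = if (!is.null(model$normalization)) {
      list(x_min = unname(model$normalization$x_min),
           x_max = unname(model$normalization$x_max))
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(payload$layer_sizes, payload$hidden_activation,
                       payload$output_activation)
  norm <- NULL
  if (!is.null(payload$normalization)) {
    norm <- structure(list(
      x_min = stats::setNames(payload$normalization$x_min, pima_feature_names()),
      x_max = stats::setNames(payload$normalization$x_max, pima_feature_names())
    ), class = "minmax_model")
  }
  structure(list(spec = spec,
                 params = decode_params(payload$flat, spec),
                 normalization = norm),
            class = "trained_model")
}
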